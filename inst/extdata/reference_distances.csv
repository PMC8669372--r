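channel,alternative,ideal,criterion,distance
physical,P1,star,C11,2.35
physical,P1,star,C12,2.35
physical,P1,star,C13,3.34
physical,P1,star,C14,2.35
physical,P1,star,C15,2.95
physical,P1,star,C16,4.24
physical,P1,star,C17,2.95
physical,P1,star,C18,2.3
physical,P1,star,C19,2.3
physical,P1,star,C110,3.1
physical,P1,star,C111,3.1
physical,P2,star,C11,9.38
physical,P2,star,C12,9.38
physical,P2,star,C13,8.54
physical,P2,star,C14,9.38
physical,P2,star,C15,6.6
physical,P2,star,C16,8.27
physical,P2,star,C17,6.6
physical,P2,star,C18,5.4
physical,P2,star,C19,5.4
physical,P2,star,C110,4.08
physical,P2,star,C111,4.08
physical,P3,star,C11,4.8
physical,P3,star,C12,4.8
physical,P3,star,C13,6.43
physical,P3,star,C14,4.97
physical,P3,star,C15,4.08
physical,P3,star,C16,5.46
physical,P3,star,C17,4.08
physical,P3,star,C18,3.38
physical,P3,star,C19,3.38
physical,P3,star,C110,2.42
physical,P3,star,C111,2.42
physical,P1,minus,C11,8.3
physical,P1,minus,C12,8.3
physical,P1,minus,C13,7.72
physical,P1,minus,C14,8.3
physical,P1,minus,C15,5.94
physical,P1,minus,C16,7.17
physical,P1,minus,C17,5.94
physical,P1,minus,C18,4.91
physical,P1,minus,C19,4.91
physical,P1,minus,C110,2.72
physical,P1,minus,C111,2.72
physical,P2,minus,C11,1.15
physical,P2,minus,C12,1.15
physical,P2,minus,C13,2.37
physical,P2,minus,C14,1.15
physical,P2,minus,C15,2.02
physical,P2,minus,C16,2.5
physical,P2,minus,C17,2.02
physical,P2,minus,C18,1.57
physical,P2,minus,C19,1.57
physical,P2,minus,C110,1.73
physical,P2,minus,C111,1.73
physical,P3,minus,C11,5.96
physical,P3,minus,C12,5.96
physical,P3,minus,C13,4.22
physical,P3,minus,C14,5.79
physical,P3,minus,C15,4.57
physical,P3,minus,C16,5.55
physical,P3,minus,C17,4.57
physical,P3,minus,C18,4.34
physical,P3,minus,C19,4.34
physical,P3,minus,C110,3.6
physical,P3,minus,C111,3.6
mental,M1,star,C21,2.35
mental,M1,star,C22,3.33
mental,M1,star,C23,3.33
mental,M1,star,C24,2.09
mental,M1,star,C25,3.34
mental,M1,star,C26,3.33
mental,M1,star,C27,2.84
mental,M1,star,C28,2.09
mental,M1,star,C29,3.24
mental,M1,star,C210,3.07
mental,M1,star,C31,2.84
mental,M1,star,C32,2.84
mental,M1,star,C33,2.84
mental,M1,star,C34,2.84
mental,M1,star,C35,2.84
mental,M1,star,C41,2.84
mental,M1,star,C42,3.49
mental,M1,star,C43,3.22
mental,M1,star,C44,2.6
mental,M1,star,C45,2.82
mental,M2,star,C21,9.38
mental,M2,star,C22,9.38
mental,M2,star,C23,9.38
mental,M2,star,C24,7.5
mental,M2,star,C25,8.54
mental,M2,star,C26,9.38
mental,M2,star,C27,6.84
mental,M2,star,C28,7.5
mental,M2,star,C29,7.5
mental,M2,star,C210,7.5
mental,M2,star,C31,6.84
mental,M2,star,C32,6.84
mental,M2,star,C33,6.84
mental,M2,star,C34,6.84
mental,M2,star,C35,6.84
mental,M2,star,C41,8.54
mental,M2,star,C42,8.54
mental,M2,star,C43,6.3
mental,M2,star,C44,4.75
mental,M2,star,C45,1.89
mental,M3,star,C21,4.8
mental,M3,star,C22,5.3
mental,M3,star,C23,5.3
mental,M3,star,C24,3.95
mental,M3,star,C25,4.97
mental,M3,star,C26,5.3
mental,M3,star,C27,4.08
mental,M3,star,C28,3.95
mental,M3,star,C29,4.59
mental,M3,star,C210,4.46
mental,M3,star,C31,3.95
mental,M3,star,C32,3.95
mental,M3,star,C33,3.95
mental,M3,star,C34,3.95
mental,M3,star,C35,3.95
mental,M3,star,C41,4.8
mental,M3,star,C42,4.8
mental,M3,star,C43,3.38
mental,M3,star,C44,2.71
mental,M3,star,C45,2.76
mental,M1,minus,C21,8.3
mental,M1,minus,C22,7.73
mental,M1,minus,C23,7.73
mental,M1,minus,C24,6.5
mental,M1,minus,C25,7.72
mental,M1,minus,C26,7.73
mental,M1,minus,C27,6.07
mental,M1,minus,C28,6.5
mental,M1,minus,C29,5.78
mental,M1,minus,C210,5.96
mental,M1,minus,C31,6.07
mental,M1,minus,C32,6.07
mental,M1,minus,C33,6.07
mental,M1,minus,C34,6.07
mental,M1,minus,C35,6.07
mental,M1,minus,C41,7.55
mental,M1,minus,C42,7.55
mental,M1,minus,C43,5.88
mental,M1,minus,C44,4.31
mental,M1,minus,C45,1.23
mental,M2,minus,C21,1.15
mental,M2,minus,C22,1.15
mental,M2,minus,C23,1.15
mental,M2,minus,C24,0.92
mental,M2,minus,C25,2.37
mental,M2,minus,C26,1.15
mental,M2,minus,C27,1.89
mental,M2,minus,C28,0.92
mental,M2,minus,C29,0.92
mental,M2,minus,C210,0.92
mental,M2,minus,C31,1.89
mental,M2,minus,C32,1.89
mental,M2,minus,C33,1.89
mental,M2,minus,C34,1.89
mental,M2,minus,C35,1.89
mental,M2,minus,C41,2.37
mental,M2,minus,C42,2.37
mental,M2,minus,C43,2.52
mental,M2,minus,C44,1.88
mental,M2,minus,C45,2.4
mental,M3,minus,C21,5.96
mental,M3,minus,C22,5.7
mental,M3,minus,C23,5.7
mental,M3,minus,C24,4.7
mental,M3,minus,C25,5.79
mental,M3,minus,C26,5.7
mental,M3,minus,C27,4.57
mental,M3,minus,C28,4.7
mental,M3,minus,C29,4.33
mental,M3,minus,C210,4.45
mental,M3,minus,C31,4.7
mental,M3,minus,C32,4.7
mental,M3,minus,C33,4.7
mental,M3,minus,C34,4.7
mental,M3,minus,C35,4.7
mental,M3,minus,C41,5.96
mental,M3,minus,C42,5.96
mental,M3,minus,C43,5.71
mental,M3,minus,C44,4.19
mental,M3,minus,C45,1.26
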