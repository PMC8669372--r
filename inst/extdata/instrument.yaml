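# 31-item screening instrument: four criterion groups, five ordered answer
# levels per item, declared least-symptomatic first. The level vocabularies
# are the package's documented defaults; any instrument file with the same
# structure can be loaded in their place.
criteria:
  - {id: C11, group: physical, text: "Regularity of periods",
     levels: ["very regular", "mostly regular", "sometimes irregular", "fairly irregular", "quite irregular"]}
  - {id: C12, group: physical, text: "Length of the menstrual cycle",
     levels: ["26-30 days", "31-35 days", "36-40 days", "41-45 days", "more than 45 days"]}
  - {id: C13, group: physical, text: "Duration of the flow",
     levels: ["3-5 days", "5-7 days", "1-2 days", "less than a day", "more than 7 days"]}
  - {id: C14, group: physical, text: "Number of pads used per day",
     levels: ["1-2", "2-3", "3-4", "4-5", "more than 5"]}
  - {id: C15, group: physical, text: "During cycle, tendency to grow dark, coarse hair on chest and chin",
     levels: ["never", "rarely", "sometimes", "most of the times", "always"]}
  - {id: C16, group: physical, text: "Weight gain",
     levels: ["none", "slight", "moderate", "considerable", "severe"]}
  - {id: C17, group: physical, text: "Eating junk food",
     levels: ["never", "rarely", "sometimes", "most of the times", "always"]}
  - {id: C18, group: physical, text: "Meal times and eating pattern",
     levels: ["very regular", "mostly regular", "sometimes irregular", "fairly irregular", "quite irregular"]}
  - {id: C19, group: physical, text: "Sleep schedule / sleep pattern",
     levels: ["very regular", "mostly regular", "sometimes irregular", "fairly irregular", "quite irregular"]}
  - {id: C110, group: physical, text: "Family history of diabetes",
     levels: ["none", "distant relative", "grandparent", "one parent", "both parents"]}
  - {id: C111, group: physical, text: "Family history of hypertension",
     levels: ["none", "distant relative", "grandparent", "one parent", "both parents"]}
  - {id: C21, group: anxiety_depression, text: "Feel tired for no good reason",
     levels: ["none of the time", "a little of the time", "some of the time", "most of the time", "all of the time"]}
  - {id: C22, group: anxiety_depression, text: "Feel nervous",
     levels: ["none of the time", "a little of the time", "some of the time", "most of the time", "all of the time"]}
  - {id: C23, group: anxiety_depression, text: "Feel so nervous that nothing could calm you down",
     levels: ["none of the time", "a little of the time", "some of the time", "most of the time", "all of the time"]}
  - {id: C24, group: anxiety_depression, text: "Feel hopeless",
     levels: ["none of the time", "a little of the time", "some of the time", "most of the time", "all of the time"]}
  - {id: C25, group: anxiety_depression, text: "Feel restless or fidgety",
     levels: ["none of the time", "a little of the time", "some of the time", "most of the time", "all of the time"]}
  - {id: C26, group: anxiety_depression, text: "Feel so restless that you could not sit still",
     levels: ["none of the time", "a little of the time", "some of the time", "most of the time", "all of the time"]}
  - {id: C27, group: anxiety_depression, text: "Feel depressed",
     levels: ["none of the time", "a little of the time", "some of the time", "most of the time", "all of the time"]}
  - {id: C28, group: anxiety_depression, text: "Feel everything was an effort",
     levels: ["none of the time", "a little of the time", "some of the time", "most of the time", "all of the time"]}
  - {id: C29, group: anxiety_depression, text: "Feel so sad that nothing could cheer you up",
     levels: ["none of the time", "a little of the time", "some of the time", "most of the time", "all of the time"]}
  - {id: C210, group: anxiety_depression, text: "Feel worthless",
     levels: ["none of the time", "a little of the time", "some of the time", "most of the time", "all of the time"]}
  - {id: C31, group: social_phobia, text: "Intense and persistent fear that others might evaluate you",
     levels: ["never", "rarely", "sometimes", "most of the times", "always"]}
  - {id: C32, group: social_phobia, text: "Fear of being humiliated in social situations",
     levels: ["never", "rarely", "sometimes", "most of the times", "always"]}
  - {id: C33, group: social_phobia, text: "Feeling extremely self-conscious",
     levels: ["never", "rarely", "sometimes", "most of the times", "always"]}
  - {id: C34, group: social_phobia, text: "Fear that others will notice blushing/sweating",
     levels: ["never", "rarely", "sometimes", "most of the times", "always"]}
  - {id: C35, group: social_phobia, text: "Try hard to avoid social situation/interaction",
     levels: ["never", "rarely", "sometimes", "most of the times", "always"]}
  - {id: C41, group: body_image, text: "Spend a lot of time worrying about their appearance",
     levels: ["never", "rarely", "sometimes", "most of the times", "always"]}
  - {id: C42, group: body_image, text: "Experience dissatisfaction with their appearance",
     levels: ["never", "rarely", "sometimes", "most of the times", "always"]}
  - {id: C43, group: body_image, text: "Avoid wearing certain clothes because they may look fat",
     levels: ["never", "rarely", "sometimes", "most of the times", "always"]}
  - {id: C44, group: body_image, text: "Compares their appearance with others and feel low",
     levels: ["never", "rarely", "sometimes", "most of the times", "always"]}
  - {id: C45, group: body_image, text: "Dissatisfaction and self-consciousness of appearance interferes with social activities and interactions",
     levels: ["never", "rarely", "sometimes", "most of the times", "always"]}
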