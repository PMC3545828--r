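Probability of achieving Hit to Lead milestone	0.80
Probability of achieving Lead Optimization milestone	0.75
Probability of achieving Preclinical Development milestone	0.85
Percentage of follow-on Hit to Lead projects	0.25
Percentage of chemistry-driven Hit to Lead projects	0.5
Percentage of prioritized Lead Optimization projects	0
Target no. Hit to Lead CHEMISTS (chemistry-driven) per team	2
Target no. Hit to Lead BIOLOGISTS (chemistry-driven) per team	3
Target no. Hit to Lead CHEMISTS (biology-driven) per team	1
Target no. Hit to Lead BIOLOGISTS (biology-driven) per team	3
Target no. Hit to Lead CHEMISTS (follow-on) per team	2
Target no. Hit to Lead BIOLOGISTS (follow-on) per team	1
Target no. Lead Optimization CHEMISTS per team	4
Target no. Lead Optimization BIOLOGISTS per team	4
No. simultaneous Lead Optimization projects supported by DMPK	0
Percent impact on timeline by DMPK support	0.1
Target cycle time (months) to achieve Lead Optimization	18
Target cycle time (months) to achieve Preclinical Development	24
Group size at 75% FTE efficiency	20
Group size at 50% FTE efficiency	40
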