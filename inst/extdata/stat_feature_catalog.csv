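name,group
Inclusion Lines,eligibility
Inclusion Words,eligibility
Average Inclusion Words,eligibility
Inclusion Numbers,eligibility
Exclusion Lines,eligibility
Exclusion Words,eligibility
Average Exclusion Words,eligibility
Exclusion Numbers,eligibility
Eligibility Lines,eligibility
Eligibility Words,eligibility
Average Eligibility Words,eligibility
Eligibility Numbers,eligibility
No Eligibility Requirement,eligibility
Gender Restriction,eligibility
Age Restriction,eligibility
Healthy Volunteer,eligibility
No Phase,study_information
Early Phase 1,study_information
Phase 1,study_information
Phase 1/2,study_information
Phase 2,study_information
Phase 2/3,study_information
Phase 3,study_information
Phase 4,study_information
Expanded Access,study_information
Data Monitoring Committee,study_information
FDA Regulated,study_information
Interventional Study,study_information
USA Study,study_information
Industry Sponsor,administrative
Industry Collaborator,administrative
Number Collaborators,administrative
Number Officials,administrative
Responsible Party: Sponsor,administrative
Number Arms,study_design
Number Countries,study_design
Number Sites,study_design
Random Groups,study_design
Masked Groups,study_design
Placebo Group,study_design
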