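heading	category
BACKGROUND	background
INTRODUCTION	background
CONTEXT	background
RATIONALE	background
IMPORTANCE	background
OBJECTIVE	objective
OBJECTIVES	objective
AIM	objective
AIMS	objective
AIMS AND OBJECTIVES	objective
PURPOSE	objective
GOAL	objective
HYPOTHESIS	objective
STUDY OBJECTIVE	objective
METHODS	methods
METHOD	methods
MATERIALS AND METHODS	methods
METHODS AND MATERIALS	methods
PATIENTS AND METHODS	methods
SUBJECTS AND METHODS	methods
DESIGN	methods
STUDY DESIGN	methods
DESIGN AND METHODS	methods
SETTING	methods
PARTICIPANTS	methods
PATIENTS	methods
SUBJECTS	methods
INTERVENTION	methods
INTERVENTIONS	methods
MAIN OUTCOME MEASURES	methods
MAIN OUTCOME MEASURE	methods
OUTCOME MEASURES	methods
MEASUREMENTS	methods
PROCEDURES	methods
STATISTICAL ANALYSIS	methods
DATA ANALYSIS	methods
RESULTS	results
FINDINGS	results
MAIN RESULTS	results
OUTCOMES	results
RESULTS AND FINDINGS	results
CONCLUSIONS	conclusions
CONCLUSION	conclusions
INTERPRETATION	conclusions
DISCUSSION	conclusions
CONCLUSIONS AND RELEVANCE	conclusions
CLINICAL IMPLICATIONS	conclusions
IMPLICATIONS	conclusions
SIGNIFICANCE	conclusions
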