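"id","name","category","definition"
1,"Anatomy","Cognition","Discussion of the patient anatomy and its structures"
2,"Planning","Cognition","Discussion of the surgical plan or approach"
3,"Mental Model","Cognition","Statements about the internal visual representation of the case"
4,"Confirmation","Cognition","Verifying an anatomical structure or prior impression"
5,"Uncertainty","Cognition","Expressing doubt or an open question about the case"
6,"Path Finding","Cognition","Verbalized intent to trace a path between anatomical features"
7,"Excitement","Emotion","Enthusiastic or positive exclamation"
8,"Frustration","Emotion","Expression of annoyance, usually with the tool"
9,"Confidence","Emotion","Statement of confidence in the case or plan"
10,"3D Manipulation","3D Interaction","Slicing, scaling or rotating the 3D model"
11,"Tool Usage","3D Interaction","Use of a tool in the 3D environment"
12,"Orienting","3D Interaction","Moving or turning to change viewpoint"
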