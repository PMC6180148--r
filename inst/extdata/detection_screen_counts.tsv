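measure	total	negative	neutral	positive
odor discrimination	5	0	0	5
marker cue	5	0	0	5
causal reasoning (visual)	4	0	0	4
arm pointing	4	0	0	4
memory-distraction	5	1	0	4
working memory	5	1	0	4
odor control trials	2	0	0	2
inferential reasoning	2	0	1	1
affect discrimination	2	0	1	1
spatial transpositions	3	0	2	1
laterality: first step	1	0	0	1
causal reasoning (auditory)	2	1	0	1
reaching	2	1	0	1
perspective-taking (obey command)	2	1	0	1
cylinder	0	0	0	0
retrieval	1	0	1	0
rotation	2	1	0	1
unsolvable task (look at experimenter)	3	2	0	1
spatial perseveration	5	3	0	2
perspective-taking (steal food)	1	1	0	0
transparent obstacle	10	5	1	4
detour navigation	1	1	0	0
social referencing	1	1	0	0
gaze direction	1	1	0	0
sensory bias	3	2	0	1
visual discrimination	6	3	1	2
contagious yawning	6	4	0	2
laterality: object manipulation	2	2	0	0
unsolvable task (manipulate container)	6	6	0	0
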