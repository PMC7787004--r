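table,pair,role,has_nap,e_l,regime,strength,resting_mv,frequency_hz
1,1,In1,1,-69,B,0,-66,0.2
1,1,In1,1,-69,B,0.05,-66,0.2
1,1,In1,1,-69,B,0.1,-66.1,0.16
1,1,In1,1,-69,B,0.2,-66.4,0.14
1,1,In2,1,-72.2,S,0,-71,NA
1,1,In2,1,-72.2,S,0.05,-70.5,0.08
1,1,In2,1,-72.2,S,0.1,-70.2,0.16
1,1,In2,1,-72.2,S,0.2,-70,0.14
1,2,In1,1,-69,B,0,-66,0.2
1,2,In1,1,-69,B,0.05,-66.4,0.2
1,2,In1,1,-69,B,0.1,-66.4,0.35
1,2,In1,1,-69,B,0.2,-66.4,0.33
1,2,In2,1,-65.5,B,0,-62.7,0.43
1,2,In2,1,-65.5,B,0.05,-62.8,0.36
1,2,In2,1,-65.5,B,0.1,-62.9,0.35
1,2,In2,1,-65.5,B,0.2,-62.9,0.33
1,3,In1,1,-69,B,0,-66,0.2
1,3,In1,1,-69,B,0.05,-65.8,0.2
1,3,In1,1,-69,B,0.1,-67,0.39
1,3,In1,1,-69,B,0.2,-66.5,0.36
1,3,In2,1,-64.9,T,0,-55.4,NA
1,3,In2,1,-64.9,T,0.05,-61.8,0.44
1,3,In2,1,-64.9,T,0.1,-61.9,0.39
1,3,In2,1,-64.9,T,0.2,-62.7,0.36
1,4,In1,1,-71.4,S,0,-69.3,NA
1,4,In1,1,-71.4,S,0.05,-67,0.05
1,4,In1,1,-71.4,S,0.1,-66.5,0.1
1,4,In1,1,-71.4,S,0.2,-66,0.13
1,4,In2,0,-59.6,S,0,-57,NA
1,4,In2,0,-59.6,S,0.05,-58.5,0.05
1,4,In2,0,-59.6,S,0.1,-59.1,0.1
1,4,In2,0,-59.6,S,0.2,-59.9,0.13
1,5,In1,1,-69,B,0,-66,0.2
1,5,In1,1,-69,B,0.05,-65.8,0.22
1,5,In1,1,-69,B,0.1,-65.6,0.23
1,5,In1,1,-69,B,0.2,-65.2,0.25
1,5,In2,0,-59.6,S,0,-57,NA
1,5,In2,0,-59.6,S,0.05,-58.3,0.22
1,5,In2,0,-59.6,S,0.1,-58.7,0.23
1,5,In2,0,-59.6,S,0.2,-59.8,0.25
1,6,In1,1,-69,B,0,-66,0.2
1,6,In1,1,-69,B,0.05,-65.8,0.22
1,6,In1,1,-69,B,0.1,-65.6,0.24
1,6,In1,1,-69,B,0.2,-65,0.26
1,6,In2,0,-59.3,T,0,-56.1,NA
1,6,In2,0,-59.3,T,0.05,-57.7,0.22
1,6,In2,0,-59.3,T,0.1,-58.5,0.24
1,6,In2,0,-59.3,T,0.2,-58.3,0.26
2,1,In1,1,-65.5,B,0,-62.7,0.43
2,1,In1,1,-65.5,B,0.5,-62.7,0.43
2,1,In1,1,-65.5,B,1,-62.7,0.43
2,1,In1,1,-65.5,B,2,-62.7,0.43
2,1,In2,1,-71.4,S,0,-69.3,NA
2,1,In2,1,-71.4,S,0.5,-70.5,0.2
2,1,In2,1,-71.4,S,1,-63.1,0.43
2,1,In2,1,-71.4,S,2,-63.1,0.43
2,2,In1,1,-65.5,B,0,-62.7,0.43
2,2,In1,1,-65.5,B,0.5,-62.7,0.43
2,2,In1,1,-65.5,B,1,-62.7,0.43
2,2,In1,1,-65.5,B,2,-62.7,0.43
2,2,In2,1,-69,B,0,-66,0.2
2,2,In2,1,-69,B,0.5,-68.3,0.43
2,2,In2,1,-69,B,1,-68.3,0.43
2,2,In2,1,-69,B,2,-68.3,0.43
2,3,In1,1,-65.5,B,0,-62.7,0.43
2,3,In1,1,-65.5,B,0.5,-62.7,0.43
2,3,In1,1,-65.5,B,1,-62.7,0.43
2,3,In1,1,-65.5,B,2,-62.7,0.43
2,3,In2,1,-64.9,T,0,-55.4,NA
2,3,In2,1,-64.9,T,0.5,-61.7,0.43
2,3,In2,1,-64.9,T,1,-61.7,0.43
2,3,In2,1,-64.9,T,2,-61.7,0.43
2,4,In1,1,-65.5,B,0,-62.7,0.43
2,4,In1,1,-65.5,B,0.5,-62.7,0.43
2,4,In1,1,-65.5,B,1,-62.7,0.43
2,4,In1,1,-65.5,B,2,-62.7,0.43
2,4,In2,0,-59.6,S,0,-57,NA
2,4,In2,0,-59.6,S,0.5,-57,0.43
2,4,In2,0,-59.6,S,1,-57,0.43
2,4,In2,0,-59.6,S,2,-57,0.43
2,5,In1,1,-65.5,B,0,-62.7,0.43
2,5,In1,1,-65.5,B,0.5,-62.7,0.43
2,5,In1,1,-65.5,B,1,-62.7,0.43
2,5,In1,1,-65.5,B,2,-62.7,0.43
2,5,In2,0,-59.3,T,0,-56.1,NA
2,5,In2,0,-59.3,T,0.5,-56.1,0.43
2,5,In2,0,-59.3,T,1,-56.1,0.43
2,5,In2,0,-59.3,T,2,-56.1,0.43
2,6,In1,0,-58.4,T,0,-55.2,NA
2,6,In1,0,-58.4,T,0.5,-55.2,NA
2,6,In1,0,-58.4,T,1,-55.2,NA
2,6,In1,0,-58.4,T,2,-55.2,NA
2,6,In2,1,-72.2,S,0,-71,NA
2,6,In2,1,-72.2,S,0.5,-70.5,NA
2,6,In2,1,-72.2,S,1,-70,NA
2,6,In2,1,-72.2,S,2,-68.5,NA
2,7,In1,0,-58.4,T,0,-55.2,NA
2,7,In1,0,-58.4,T,0.5,-55.2,NA
2,7,In1,0,-58.4,T,1,-55.2,NA
2,7,In1,0,-58.4,T,2,-55.2,NA
2,7,In2,1,-69,B,0,-66,0.2
2,7,In2,1,-69,B,0.5,-65.6,0.22
2,7,In2,1,-69,B,1,-65.1,0.25
2,7,In2,1,-69,B,2,-64.5,0.33
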