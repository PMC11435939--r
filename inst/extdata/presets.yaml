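# Cubic rep-percentage coefficient presets (trained older adults with
# osteopenia/osteoporosis, proxomed compass 600 machines).
# Each entry: p(x) = c0 + c1*x + c2*x^2 + c3*x^3, predicted 1RM = p(reps)*load;
# kappa converts an isometric maximum: predicted 1RM = kappa*ISOM.
# "pooled" is the leg-press-derived curve that transfers to all exercises.
pooled:
  exercise: pooled
  coefficients: [0.99157, 0.0104749226, 0.000739743671, -0.0000089288473]
  kappa: 1.0002929780312122
  valid_reps: [1, 16]
lat_pulls:
  exercise: lat_pulls
  coefficients: [0.987542505, 0.0152700149, 0.00278487038, -0.000115638888]
  kappa: 0.9992532650410967
  valid_reps: [1, 16]
triceps_dips:
  exercise: triceps_dips
  coefficients: [0.973559954, 0.0271642658, 0.000930880743, -0.0000477453474]
  kappa: 0.9992532650410967
  valid_reps: [1, 16]
trunk_extension:
  exercise: trunk_extension
  coefficients: [1.01565994, -0.0130808261, 0.00601883266, -0.000228623800]
  kappa: 0.9992532650410967
  valid_reps: [1, 16]
trunk_flexion:
  exercise: trunk_flexion
  coefficients: [0.994961852, 0.00731240752, 0.00293967456, -0.000105109010]
  kappa: 0.9992532650410967
  valid_reps: [1, 16]
leg_extension:
  exercise: leg_extension
  coefficients: [0.999714613, 0.00184050532, 0.00390281962, -0.000128405344]
  kappa: 0.9992532650410967
  valid_reps: [1, 16]
leg_flexion:
  exercise: leg_flexion
  coefficients: [0.994637813, 0.00715193846, 0.00333621122, -0.000109143358]
  kappa: 0.9992532650410967
  valid_reps: [1, 16]
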