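ranges:
  darkest:
    r:
    - 40
    - 120
    g:
    - 20
    - 90
    b:
    - 0
    - 70
  mid:
    r:
    - 121
    - 170
    g:
    - 80
    - 130
    b:
    - 40
    - 100
  light:
    r:
    - 171
    - 215
    g:
    - 120
    - 170
    b:
    - 70
    - 135
  negative:
    r:
    - 60
    - 160
    g:
    - 70
    - 170
    b:
    - 130
    - 230
  widePositive:
    r:
    - 40
    - 215
    g:
    - 20
    - 170
    b:
    - 0
    - 135
  bg1:
    r:
    - 40
    - 215
    g:
    - 20
    - 170
    b:
    - 0
    - 135
  bg2:
    r:
    - 171
    - 230
    g:
    - 120
    - 185
    b:
    - 70
    - 150
filters:
  map1:
    area:
    - 80.0
    - 5000.0
    roundness:
    - 1.0
    - 3.0
  map2:
    area:
    - 80.0
    - 5000.0
    roundness:
    - 1.0
    - 3.0
  map3:
    area:
    - 80.0
    - 5000.0
    roundness:
    - 1.0
    - 3.0
  final:
    area:
    - 80.0
    - 1200.0
    roundness:
    - 1.0
    - 1.6
  wide:
    area:
    - 80.0
    - 5000.0
    roundness:
    - 1.0
    - 3.0
ratio_threshold: 0.2
sentinel_color:
- 0
- 255
- 0
mean_nucleus_area: auto
cluster_factor: 1.5
complexity_cutoff: 100
fill_holes: no
exclude_border: no
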