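fps: 15
image_width: 800
image_height: 600
criterion: area
gap_tolerance: 0
feeding_area:
  cx: 400
  cy: 300
  r: 60
tracking_area:
  x: [50, 750, 750, 50]
  y: [50, 50, 550, 550]
tracker:
  match_radius: 20
  max_missed: 10
  history_length: 10
  min_confidence: 0.5
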