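# YOLOv5s baseline (v4-era dialect: Focus, C3, SPP(5,9,13), SiLU),
# nominal channels scaled by width_multiple, repeats by depth_multiple.
name: yolov5s
nc: 20
img_size: 640
depth_multiple: 0.33
width_multiple: 0.50
anchors:
  - [10, 13, 16, 30, 33, 23]
  - [30, 61, 62, 45, 59, 119]
  - [116, 90, 156, 198, 373, 326]
layers:
  - [-1, 1, Focus, [64, 3]]              # 0
  - [-1, 1, Conv, [128, 3, 2]]           # 1
  - [-1, 3, C3, [128]]                   # 2
  - [-1, 1, Conv, [256, 3, 2]]           # 3
  - [-1, 9, C3, [256]]                   # 4
  - [-1, 1, Conv, [512, 3, 2]]           # 5
  - [-1, 9, C3, [512]]                   # 6
  - [-1, 1, Conv, [1024, 3, 2]]          # 7
  - [-1, 1, SPP, [1024, [5, 9, 13]]]     # 8
  - [-1, 3, C3, [1024, false]]           # 9
  - [-1, 1, Conv, [512, 1, 1]]           # 10
  - [-1, 1, UpSample, [~, 2, nearest]]   # 11
  - [[-1, 6], 1, Concat, [1]]            # 12
  - [-1, 3, C3, [512, false]]            # 13
  - [-1, 1, Conv, [256, 1, 1]]           # 14
  - [-1, 1, UpSample, [~, 2, nearest]]   # 15
  - [[-1, 4], 1, Concat, [1]]            # 16
  - [-1, 3, C3, [256, false]]            # 17
  - [-1, 1, Conv, [256, 3, 2]]           # 18
  - [[-1, 14], 1, Concat, [1]]           # 19
  - [-1, 3, C3, [512, false]]            # 20
  - [-1, 1, Conv, [512, 3, 2]]           # 21
  - [[-1, 10], 1, Concat, [1]]           # 22
  - [-1, 3, C3, [1024, false]]           # 23
detect: [17, 20, 23]
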