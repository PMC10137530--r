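# Reduced-width variant of the lite architecture (same block vocabulary:
# stem, rep, CoT3, SPP, SimAM) sized for CPU-scale training experiments.
# Strides 16/32/64 mirror the stem-entry lite model; at the 128-px network
# input the anchors span one to five grid cells per scale, the regime the
# anchor mechanism is designed for. Each detect tap reads
# the backbone features concatenated with a fixed random 1x1-conv expansion
# (a random-feature basis for the trainable head).
name: gl_yolo_lite_tiny
nc: 1
img_size: 128
depth_multiple: 1.0
width_multiple: 1.0
anchors:
  - [10, 13, 16, 30, 33, 23]
  - [30, 61, 62, 45, 59, 119]
  - [116, 90, 156, 198, 373, 326]
layers:
  - [-1, 1, Stem, [24, 3]]               # 0  stride 4
  - [-1, 1, Rep, [32, 3, 2]]             # 1  stride 8
  - [-1, 1, CoT3, [32]]                  # 2
  - [-1, 1, Rep, [48, 3, 2]]             # 3  stride 16
  - [-1, 1, CoT3, [48]]                  # 4
  - [-1, 1, Rep, [64, 3, 2]]             # 5  stride 32
  - [-1, 1, CoT3, [64]]                  # 6
  - [-1, 1, Rep, [96, 3, 2]]             # 7  stride 64
  - [-1, 1, SPP, [96, [5, 9, 13]]]       # 8
  - [-1, 1, CoT3, [96, false]]           # 9
  - [9, 1, SimAM, [96]]                  # 10
  - [4, 1, Conv, [160, 3, 1]]            # 11 random feature expansion (P3)
  - [[4, 11], 1, Concat, [1]]            # 12 P3 tap, stride 16
  - [6, 1, Conv, [160, 3, 1]]            # 13 random feature expansion (P4)
  - [[6, 13], 1, Concat, [1]]            # 14 P4 tap, stride 32
  - [10, 1, Conv, [160, 3, 1]]           # 15 random feature expansion (P5)
  - [[10, 15], 1, Concat, [1]]           # 16 P5 tap, stride 64
detect: [12, 14, 16]
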