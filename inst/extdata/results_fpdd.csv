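method,backbone,map50,fps_gpu,fps_cpu,params,gflops
YOLOv5-mbv3-small,MobileNetv3-small,80.1,55.25,13.40,3.54,6.3
YOLOv5-mbv3-large,MobileNetv3-large,83.9,47.62,7.50,5.2,10.3
YOLOv5-ShuffleNetv2,ShuffleNetv2,70.9,52.91,18.32,0.44,1.3
YOLOv3-Tiny,Darknet-53,69.6,243.90,6.83,8.67,12.9
YOLOv5-s,CSPDarknet-SPP,85.7,73.53,7.03,7.05,16.3
YOLOv5-lite-g,RepVGG,85.5,62.89,6.98,5.3,15.1
YOLOv5s-Ghost,GhostNet,86.1,56.18,7.71,3.68,8.1
GL-YOLO,GL-YOLO,89.1,49.75,5.51,7.03,16.2
GL-YOLO-Lite,GL-YOLO,88.5,52.63,9.89,4.41,3.3
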