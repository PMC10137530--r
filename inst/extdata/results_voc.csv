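method,backbone,map50,fps_gpu,fps_cpu,params,gflops
YOLOv5-mbv3-small,MobileNetv3-small,69.1,61.35,15.11,3.59,6.4
YOLOv5-mbv3-large,MobileNetv3-large,77,54.95,8.01,5.25,10.3
YOLOv5-ShuffleNetv2,ShuffleNetv2,56.7,61.35,19.19,0.45,1.4
YOLOv3-Tiny,Darknet-53,57.7,277.78,7.58,8.71,13
YOLOv5-s,CSPDarknet-SPP,77.8,69.93,8.08,7.11,16.4
YOLOv5-lite-g,RepVGG,78.2,70.42,7.86,5.32,15.3
YOLOv5s-Ghost,GhostNet,77,61.73,8.29,3.73,8.3
GL-YOLO,GL-YOLO,82.5,51.55,6.43,7.08,16.4
GL-YOLO-Lite,GL-YOLO,80,56.82,11.07,4.42,3.4
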