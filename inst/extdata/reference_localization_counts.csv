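detector,gt_total,matched_075
yolo11n,5603,5488
yolo26n,5603,5508
rfdetr_nano,5603,5154
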