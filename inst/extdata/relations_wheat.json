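["Growth period", "Winter-spring type", "Plant height", "Maturity",
 "Spike number per mu", "Shell color", "Kernel number", "Seed color",
 "1000-grain weight", "Grain hardness", "Unit weight", "Grain shape",
 "Stability time", "Awn length", "Tensile area", "Leaf color", "Yield",
 "Plant type", "Sowing time", "Crude protein content", "Seeding quantity",
 "Wet gluten content", "Disease susceptibility"]
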