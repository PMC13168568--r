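File type = "ooTextFile"
Object class = "TextGrid"

xmin = 0
xmax = 1
tiers? <exists>
size = 2
item []:
    item [1]:
        class = "IntervalTier"
        name = "word"
        xmin = 0
        xmax = 1
        intervals: size = 2
        intervals [1]:
            xmin = 0
            xmax = 0.5
            text = "ba"
        intervals [2]:
            xmin = 0.5
            xmax = 1
            text = "da"
    item [2]:
        class = "IntervalTier"
        name = "phoneme"
        xmin = 0
        xmax = 1
        intervals: size = 4
        intervals [1]:
            xmin = 0
            xmax = 0.25
            text = "b"
        intervals [2]:
            xmin = 0.25
            xmax = 0.5
            text = "a"
        intervals [3]:
            xmin = 0.5
            xmax = 0.75
            text = "d"
        intervals [4]:
            xmin = 0.75
            xmax = 1
            text = "a"
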