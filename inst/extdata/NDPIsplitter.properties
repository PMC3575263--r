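# Default configuration of the slide splitter.
# Tile geometry is interpreted at the output magnification.
tile.width=300
tile.height=300
# Split at scan magnification unless overridden here.
# magnification=20

# Assumed scan magnification for containers without a magnification tag.
default.magnification=40

# Empty-tile filter: none, intensity (fluorescent) or compression (brightfield).
empty.filter=compression

# Intensity algorithm thresholds (0..255 scale).
empty.intensity.avg=10
empty.intensity.whiteness=30
empty.intensity.minfraction=0.01

# Compression algorithm thresholds.
empty.compression.quality=75
empty.compression.ratio=0.02
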