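# Snapshot Creator workflow configuration.
folder.root=archive
# Individual folders may be overridden; defaults live under folder.root:
# folder.ndpi.new=archive/NDPI-New
# folder.publish=archive/publish

store.path=archive/specimens.tsv

# Snapshot output: centered quarter of the slide at this magnification.
snapshot.magnification=10
snapshot.quality=90
# watermark.path=logo.png

default.magnification=40
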