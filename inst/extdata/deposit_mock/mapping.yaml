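# Mapping for the bundled SYNTHETIC mock of an external spectra deposit.
# The real deposit must be downloaded manually; this mock only exercises
# the adapter code path.
type: csv_dir
pattern: "cmpd*.csv"
wavenumber_column: wavenumber
intensity_column: absorbance
metadata: metadata.csv
phase: liquid
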