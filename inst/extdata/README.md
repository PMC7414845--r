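# External data

Calibration curves are third-party datasets and are not bundled. To
calibrate against IntCal13, download `intcal13.14c` (the standard
comma-separated IntCal distribution file) and place it in this directory;
`read_intcal()` and the radiocarbon acceptance check will pick it up via
`system.file("extdata", "intcal13.14c", package = "paleocanid")`.

Synthetic fixtures are never stored here: they are generated at run time
by the `gen_*` functions and `simulate_fixtures()`.
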