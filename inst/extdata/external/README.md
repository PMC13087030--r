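# External inputs (not shipped)

Two analyses consume deposited experimental data that cannot be bundled:

* `pdb_00008x1c.cif` — the cryo-EM structure of the remodeler-bound
  nucleosome (download from RCSB PDB and place here) for the DNA
  accessibility ratio at 20-30 A probe radii.
* `nanog_tracks/ctrl/` and `nanog_tracks/iaa/` — single-molecule track
  exports, each containing `fast.tsv`, `continuous.tsv`, `timelapse.tsv`
  with YAML sidecars as written by `chromakit::write_tracks()`, for the
  binding-frequency contrast.

The corresponding tests in `tests/testthat/test-acceptance.R` run the real
computation when these files are present and report their absence otherwise.
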