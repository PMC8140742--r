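.onLoad <- function(libname, pkgname) {
  .register_composition_encoders()
  .register_physchem_encoders()
  .register_autocorr_encoders()
  .register_order_encoders()
  .register_residue_encoders()
}
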