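# Minimal paired cohort built from explicit glaucoma/control value vectors.
pair_table <- function(glaucoma, control, variable = "offset_index") {
  n <- length(glaucoma)
  out <- tibble::tibble(
    patient_id = rep(sprintf("P%03d", seq_len(n)), each = 2),
    eye_role = rep(c("glaucoma", "control"), n)
  )
  out[[variable]] <- as.vector(rbind(glaucoma, control))
  out
}
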