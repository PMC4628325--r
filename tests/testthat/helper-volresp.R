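# shared fixtures for the suite

k_default <- 0.3 / 1.96

# a tiny deterministic three-reader cohort built by hand:
# two patients, baseline + two follow-ups
tiny_cohort <- function() {
  tidyr::expand_grid(
    patient_id = c("A", "B"),
    lesion_id = "L1",
    reader_id = c("R1", "R2", "R3"),
    timepoint_index = 0:2
  ) |>
    dplyr::mutate(
      volume_cm3 = dplyr::case_when(
        patient_id == "A" & timepoint_index == 0 ~ 100,
        patient_id == "A" & timepoint_index == 1 ~ 50,
        patient_id == "A" & timepoint_index == 2 ~ 70,
        patient_id == "B" ~ 20
      )
    )
}
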