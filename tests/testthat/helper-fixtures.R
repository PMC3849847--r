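# Builders for hand-crafted admission and medical-record rows, so tests can
# state tiny histories explicitly.

make_admission <- function(person_id, admission_id, admission_date,
                           principal = "486", secondary = character(0),
                           icd_version = NULL, los = 3,
                           indigenous_flag = FALSE, age = 60, sex = "male",
                           admission_type = "emergency",
                           hospital_type = "public",
                           hospital_location = "metropolitan",
                           transfer_in = FALSE, transfer_out = FALSE,
                           died_in_hospital = FALSE) {
  admission_date <- as.Date(admission_date)
  icd_version <- icd_version %||%
    (if (admission_date >= as.Date("1999-07-01")) 10L else 9L)
  tibble::tibble(
    person_id = person_id,
    admission_id = admission_id,
    admission_date = admission_date,
    separation_date = admission_date + los,
    icd_version = as.integer(icd_version),
    principal_diagnosis = principal,
    secondary_diagnoses = paste(secondary, collapse = ";"),
    admission_type = admission_type,
    hospital_type = hospital_type,
    hospital_location = hospital_location,
    transfer_in = transfer_in,
    transfer_out = transfer_out,
    died_in_hospital = died_in_hospital,
    indigenous_flag = indigenous_flag,
    age = age,
    sex = sex
  )
}

make_medical_record <- function(person_id, index_admission_id,
                                documented = "absent", drug = FALSE) {
  tibble::tibble(
    person_id = person_id,
    index_admission_id = index_admission_id,
    diabetes_documented = documented,
    diabetes_drug_treatment = drug
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small simulated dataset shared by property-style tests
small_sim <- function(seed = 401, n9 = 250, n10 = 350, ...) {
  cfg <- lookback::sim_config(
    n_patients_per_era = c(ICD9 = n9, ICD10 = n10),
    seed = seed, ...
  )
  list(cfg = cfg, dat = lookback::generate_linked_data(cfg))
}
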