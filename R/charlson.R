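# Quan-style ICD-9-CM / ICD-10 coding of the 17 Charlson conditions, with
# the original Charlson weights. Stored as prefix lists: a diagnosis code
# matches a condition if, after normalization (upper-case, punctuation
# stripped), it starts with any listed prefix. Hierarchies are applied in
# charlson_index(): complicated diabetes supersedes uncomplicated,
# moderate/severe liver disease supersedes mild, and metastatic solid
# tumour supersedes any malignancy.

charlson_conditions <- list(
  mi = list(
    weight = 1, icd9 = c("410", "412"),
    icd10 = c("I21", "I22", "I252")
  ),
  chf = list(
    weight = 1,
    icd9 = c(
      "39891", "40201", "40211", "40291", "40401", "40403", "40411",
      "40413", "40491", "40493", "4254", "4255", "4256", "4257", "4258",
      "4259", "428"
    ),
    icd10 = c(
      "I099", "I110", "I130", "I132", "I255", "I420", "I425", "I426",
      "I427", "I428", "I429", "I43", "I50", "P290"
    )
  ),
  pvd = list(
    weight = 1,
    icd9 = c(
      "0930", "4373", "440", "441", "4431", "4432", "4433", "4434",
      "4435", "4436", "4437", "4438", "4439", "4471", "5571", "5579",
      "V434"
    ),
    icd10 = c(
      "I70", "I71", "I731", "I738", "I739", "I771", "I790", "I792",
      "K551", "K558", "K559", "Z958", "Z959"
    )
  ),
  cvd = list(
    weight = 1,
    icd9 = c("36234", "430", "431", "432", "433", "434", "435", "436",
      "437", "438"),
    icd10 = c("G45", "G46", "H340", paste0("I6", 0:9))
  ),
  dementia = list(
    weight = 1,
    icd9 = c("290", "2941", "3312"),
    icd10 = c("F00", "F01", "F02", "F03", "F051", "G30", "G311")
  ),
  copd = list(
    weight = 1,
    icd9 = c("4168", "4169", as.character(490:505), "5064", "5081", "5088"),
    icd10 = c(
      "I278", "I279", paste0("J4", 0:7), paste0("J6", 0:7),
      "J684", "J701", "J703"
    )
  ),
  rheumatic = list(
    weight = 1,
    icd9 = c(
      "4465", "7100", "7101", "7102", "7103", "7104", "7140", "7141",
      "7142", "7148", "725"
    ),
    icd10 = c("M05", "M06", "M315", "M32", "M33", "M34", "M351", "M353",
      "M360")
  ),
  peptic_ulcer = list(
    weight = 1, icd9 = c("531", "532", "533", "534"),
    icd10 = c("K25", "K26", "K27", "K28")
  ),
  mild_liver = list(
    weight = 1,
    icd9 = c(
      "07022", "07023", "07032", "07033", "07044", "07054", "0706",
      "0709", "570", "571", "5733", "5734", "5738", "5739", "V427"
    ),
    icd10 = c(
      "B18", "K700", "K701", "K702", "K703", "K709", "K713", "K714",
      "K715", "K717", "K73", "K74", "K760", "K762", "K763", "K764",
      "K768", "K769", "Z944"
    )
  ),
  diabetes_uncomplicated = list(
    weight = 1,
    icd9 = c("2500", "2501", "2502", "2503", "2508", "2509"),
    icd10 = as.vector(outer(paste0("E1", 0:4), c("0", "1", "6", "8", "9"),
      paste0))
  ),
  diabetes_complicated = list(
    weight = 2,
    icd9 = c("2504", "2505", "2506", "2507"),
    icd10 = as.vector(outer(paste0("E1", 0:4), c("2", "3", "4", "5", "7"),
      paste0))
  ),
  hemiplegia = list(
    weight = 2,
    icd9 = c(
      "3341", "342", "343", "3440", "3441", "3442", "3443", "3444",
      "3445", "3446", "3449"
    ),
    icd10 = c(
      "G041", "G114", "G801", "G802", "G81", "G82", "G830", "G831",
      "G832", "G833", "G834", "G839"
    )
  ),
  renal = list(
    weight = 2,
    icd9 = c(
      "40301", "40311", "40391", "40402", "40412", "40492", "582",
      "5830", "5831", "5832", "5833", "5834", "5835", "5836", "5837",
      "585", "586", "5880", "V420", "V451", "V56"
    ),
    icd10 = c(
      "I120", "I131", "N032", "N033", "N034", "N035", "N036", "N037",
      "N052", "N053", "N054", "N055", "N056", "N057", "N18", "N19",
      "N250", "Z490", "Z491", "Z492", "Z940", "Z992"
    )
  ),
  malignancy = list(
    weight = 2,
    icd9 = c(
      as.character(140:172), as.character(174:195), as.character(200:208),
      "2386"
    ),
    icd10 = c(
      sprintf("C%02d", c(0:26, 30:34, 37:41, 43, 45:58, 60:76)),
      "C81", "C82", "C83", "C84", "C85", "C88", "C90", "C91", "C92",
      "C93", "C94", "C95", "C96", "C97"
    )
  ),
  severe_liver = list(
    weight = 3,
    icd9 = c("4560", "4561", "4562", "5722", "5723", "5724", "5725",
      "5726", "5727", "5728"),
    icd10 = c(
      "I850", "I859", "I864", "I982", "K704", "K711", "K721", "K729",
      "K765", "K766", "K767"
    )
  ),
  metastatic = list(
    weight = 6, icd9 = c("196", "197", "198", "199"),
    icd10 = c("C77", "C78", "C79", "C80")
  ),
  aids = list(
    weight = 6, icd9 = c("042", "043", "044"),
    icd10 = c("B20", "B21", "B22", "B24")
  )
)

#' Charlson condition coding table
#'
#' The Quan-style ICD-9-CM and ICD-10 prefix mapping of the 17 Charlson
#' comorbidity conditions with their original weights, as a tidy tibble
#' (one row per condition-version-prefix).
#'
#' @return Tibble `condition`, `weight`, `icd_version`, `prefix`.
#' @export
charlson_map <- function() {
  purrr::imap(charlson_conditions, function(def, cond) {
    dplyr::bind_rows(
      tibble(
        condition = cond, weight = def$weight,
        icd_version = 9L, prefix = def$icd9
      ),
      tibble(
        condition = cond, weight = def$weight,
        icd_version = 10L, prefix = def$icd10
      )
    )
  }) |>
    dplyr::bind_rows()
}

match_condition <- function(norm_codes, prefixes) {
  any(vapply(
    prefixes,
    function(p) any(startsWith(norm_codes, p)),
    logical(1)
  ))
}

#' Charlson comorbidity index for one code set
#'
#' Sums the original Charlson weights over conditions matched (by category
#' prefix) in `codes`. Hierarchical conditions are counted once at their
#' most severe matched form (complicated vs uncomplicated diabetes,
#' moderate/severe vs mild liver disease, metastatic tumour vs any
#' malignancy). With `exclude_diabetes = TRUE` (the default here, since
#' diabetes is the condition under validation) both diabetes categories
#' contribute 0.
#'
#' @param codes Character vector of ICD codes (any punctuation).
#' @param icd_version 9 or 10.
#' @param exclude_diabetes Drop the diabetes conditions from the score.
#' @return Non-negative integer score.
#' @export
#' @examples
#' charlson_index(c("I500", "C50"), 10) # CHF (1) + malignancy (2) = 3
#' charlson_index(c("E1122"), 10, exclude_diabetes = TRUE) # 0
charlson_index <- function(codes, icd_version, exclude_diabetes = TRUE) {
  icd_version <- as.integer(icd_version)
  if (!icd_version %in% c(9L, 10L)) {
    stop("`icd_version` must be 9 or 10", call. = FALSE)
  }
  norm <- normalize_icd(codes)
  norm <- norm[nzchar(norm)]
  if (!length(norm)) {
    return(0L)
  }
  key <- if (icd_version == 9L) "icd9" else "icd10"
  hit <- vapply(
    charlson_conditions,
    function(def) match_condition(norm, def[[key]]),
    logical(1)
  )
  if (exclude_diabetes) {
    hit[c("diabetes_uncomplicated", "diabetes_complicated")] <- FALSE
  }
  # hierarchy: count only the most severe form of each condition family
  if (hit["diabetes_complicated"]) hit["diabetes_uncomplicated"] <- FALSE
  if (hit["severe_liver"]) hit["mild_liver"] <- FALSE
  if (hit["metastatic"]) hit["malignancy"] <- FALSE
  weights <- vapply(charlson_conditions, `[[`, numeric(1), "weight")
  as.integer(sum(weights[hit]))
}
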