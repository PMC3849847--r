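#' ICD diagnosis-code predicates
#'
#' Category-prefix matching for the two code sets the pipeline needs:
#' coronary heart disease (CHD; ICD-9-CM 410--414, ICD-10 I20--I25) and
#' diabetes mellitus of any type (ICD-9 250, ICD-10 E10--E14). Matching is
#' on the leading category after stripping punctuation and whitespace, so
#' sub-codes at any depth match (`"4109"`, `"250.01"`, `"E1165"`). A
#' malformed or empty code never errors: it simply fails to match.
#'
#' @param code Character vector of ICD codes.
#' @param icd_version Integer vector (9 or 10), recycled against `code`.
#'   Every code is matched under its own record's ICD version.
#' @return Logical vector.
#' @export
#' @examples
#' is_chd_code(c("4109", "414", "I259", "I26"), c(9, 9, 10, 10))
#' is_diabetes_code(c("25001", "E1165", "E15"), c(9, 10, 10))
is_chd_code <- function(code, icd_version) {
  norm <- normalize_icd(code)
  v <- rep_len(as.integer(icd_version), length(norm))
  out <- logical(length(norm))
  i9 <- v == 9L
  out[i9] <- substr(norm[i9], 1, 3) %in% as.character(410:414)
  i10 <- v == 10L
  out[i10] <- substr(norm[i10], 1, 3) %in% paste0("I", 20:25)
  out
}

#' @rdname is_chd_code
#' @export
is_diabetes_code <- function(code, icd_version) {
  norm <- normalize_icd(code)
  v <- rep_len(as.integer(icd_version), length(norm))
  out <- logical(length(norm))
  i9 <- v == 9L
  out[i9] <- substr(norm[i9], 1, 3) == "250"
  i10 <- v == 10L
  out[i10] <- substr(norm[i10], 1, 3) %in% paste0("E", 10:14)
  out
}

# Upper-case and drop everything that is not a letter or digit, so
# "E11.65" and "e1165" normalize identically. NA -> "".
normalize_icd <- function(code) {
  code <- toupper(ifelse(is.na(code), "", as.character(code)))
  gsub("[^A-Z0-9]", "", code)
}

#' Group a CHD principal diagnosis
#'
#' Classifies an index admission's principal diagnosis into myocardial
#' infarction (ICD-9 410, ICD-10 I21--I22), unstable angina (ICD-9 411,
#' ICD-10 I20.0) or other CHD.
#'
#' @inheritParams is_chd_code
#' @return Factor with levels `MI`, `UA`, `other_CHD`.
#' @export
principal_dx_group <- function(code, icd_version) {
  norm <- normalize_icd(code)
  v <- rep_len(as.integer(icd_version), length(norm))
  cat3 <- substr(norm, 1, 3)
  mi <- (v == 9L & cat3 == "410") | (v == 10L & cat3 %in% c("I21", "I22"))
  ua <- (v == 9L & cat3 == "411") |
    (v == 10L & substr(norm, 1, 4) == "I200")
  out <- ifelse(mi, "MI", ifelse(ua, "UA", "other_CHD"))
  factor(out, levels = c("MI", "UA", "other_CHD"))
}
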