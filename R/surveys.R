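#' Score financial-incentive acceptability
#'
#' Four items rated 0 (strongly disagree) to 4 (strongly agree); the fourth
#' ("incentives should not be provided...") is reverse-scored before
#' averaging. Complete-case: any missing item yields a missing score.
#'
#' @param items numeric vector or 4-column matrix/data frame of item
#'   responses in 0..4 (NA allowed)
#' @return mean acceptability in `[0, 4]`, NA where any item is missing
#' @export
acceptability_score <- function(items) {
  m <- if (is.null(dim(items))) matrix(as.numeric(items), ncol = 4) else as.matrix(items)
  if (ncol(m) != 4) stop_data("acceptability takes exactly 4 items")
  if (any(m < 0 | m > 4, na.rm = TRUE)) stop_data("acceptability items must be in 0..4")
  m[, 4] <- 4 - m[, 4]
  out <- rowMeans(m)          # NA propagates: complete-case rule
  as.numeric(out)
}

#' Flag hazardous alcohol use from an AUDIT-C score
#'
#' Gender-specific cutoffs: score >= 4 for men; >= 3 for women; >= 3 for
#' gender-minority participants (the recommended cutoff to predict alcohol
#' dependence symptoms or consequences in that group).
#'
#' @param auditc_score AUDIT-C consumption score (0..12), NA allowed
#' @param gender `"male"`, `"female"` or `"gender_minority"`
#' @return logical (NA where score missing)
#' @export
hazardous_alcohol <- function(auditc_score, gender) {
  if (any(auditc_score < 0, na.rm = TRUE)) stop_data("AUDIT-C score must be >= 0")
  bad <- setdiff(unique(gender), c("male", "female", "gender_minority"))
  if (length(bad)) stop_data("unknown gender code: %s", paste(bad, collapse = ", "))
  cutoff <- ifelse(gender == "male", 4, 3)
  auditc_score >= cutoff
}

#' PHQ-9 depressive-symptom total
#'
#' Sum of nine items each scored 0..3 (standard range 0-27). Complete-case:
#' any missing item yields NA.
#'
#' @param items numeric vector or 9-column matrix of item responses
#' @return integer totals
#' @export
phq9_total <- function(items) {
  m <- if (is.null(dim(items))) matrix(as.numeric(items), ncol = 9) else as.matrix(items)
  if (ncol(m) != 9) stop_data("PHQ-9 takes exactly 9 items")
  if (any(m < 0 | m > 3, na.rm = TRUE)) stop_data("PHQ-9 items must be in 0..3")
  as.numeric(rowSums(m))
}

#' Internalized HIV stigma mean
#'
#' Mean of items scored 1..5. Item polarity is taken as given (higher =
#' more internalized stigma under the default orientation); set
#' `reverse = TRUE` to flip a scale keyed in the other direction.
#'
#' @param items numeric vector or matrix of items in 1..5
#' @param reverse flip polarity (item -> 6 - item) before averaging
#' @return mean in `[1, 5]`, NA where any item missing
#' @export
stigma_mean <- function(items, reverse = FALSE) {
  m <- if (is.null(dim(items))) matrix(as.numeric(items), nrow = 1) else as.matrix(items)
  if (any(m < 1 | m > 5, na.rm = TRUE)) stop_data("stigma items must be in 1..5")
  if (reverse) m <- 6 - m
  as.numeric(rowMeans(m))
}

# declared score ranges, reported alongside each instrument
INSTRUMENT_RANGES <- list(
  acceptability = c(0, 4),
  auditc = c(0, 12),
  phq9 = c(0, 27),
  case = c(3, 16),
  stigma = c(1, 5)
)

#' Score all baseline instruments for a cohort
#'
#' Produces one row per participant with the mean acceptability score, the
#' hazardous-alcohol flag (gender-specific AUDIT-C cutoffs), the PHQ-9
#' total, the CASE adherence index (range 3-16; the total is accepted
#' directly as input where item-level data are unavailable) and the
#' internalized-stigma mean. Missingness propagates complete-case per
#' instrument; the attached `ranges` attribute documents each scale's range.
#'
#' @param participants tibble with columns `id`, `gender_group`,
#'   `accept_1..accept_4`, `auditc_score`, `phq9_1..phq9_9`, `case_score`,
#'   `stigma_1..stigma_4`
#' @return tibble of scores keyed by participant_id, with attribute `ranges`
#' @export
score_surveys <- function(participants) {
  acc <- acceptability_score(as.matrix(participants[paste0("accept_", 1:4)]))
  phq <- phq9_total(as.matrix(participants[paste0("phq9_", 1:9)]))
  stig <- stigma_mean(as.matrix(participants[paste0("stigma_", 1:4)]))
  cs <- as.numeric(participants$case_score)
  if (any(cs < INSTRUMENT_RANGES$case[1] | cs > INSTRUMENT_RANGES$case[2], na.rm = TRUE))
    stop_data("CASE score out of range 3..16")
  out <- tibble::tibble(
    participant_id = participants$id,
    acceptability = acc,
    auditc_score = as.numeric(participants$auditc_score),
    hazardous_alcohol = hazardous_alcohol(participants$auditc_score, participants$gender_group),
    phq9_total = phq,
    case_total = cs,
    stigma_mean = stig
  )
  attr(out, "ranges") <- INSTRUMENT_RANGES
  out
}
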