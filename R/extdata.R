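#' Published APOE4-by-amyloid cross-tabulation
#'
#' Subject counts by APOE4 allele count (0/1/2), age group and amyloid
#' status for the ADNI2 and AIBL screening samples, as published; bundled
#' so the majority-class accuracy table can be recomputed without access
#' to the restricted subject-level data.
#'
#' @param study \code{"ADNI2"}, \code{"AIBL"} or \code{"both"}.
#' @return a data frame with columns \code{study}, \code{apoe4},
#'   \code{age_group}, \code{n_negative}, \code{n_positive}.
#' @seealso \code{\link{counts_to_subjects}}, \code{\link{apoe_age_accuracy}}.
#' @export
apoe_amyloid_counts <- function(study = c("both", "ADNI2", "AIBL")) {
  study <- match.arg(study)
  tab <- utils::read.csv(system.file("extdata", "apoe_amyloid_counts.csv",
                                     package = "posetcog", mustWork = TRUE),
                         stringsAsFactors = FALSE)
  if (study != "both") tab <- tab[tab$study == study, ]
  tab
}

#' Expand a count cross-tabulation to a subject table
#'
#' Replicates each cell of an APOE4 x age-group x amyloid count table into
#' one row per subject, giving the subject-level input
#' \code{\link{apoe_age_accuracy}} consumes.
#'
#' @param counts a data frame with columns \code{apoe4}, \code{age_group},
#'   \code{n_negative}, \code{n_positive}.
#' @return a data frame with columns \code{apoe4}, \code{age_group},
#'   \code{amyloid}.
#' @export
counts_to_subjects <- function(counts) {
  need <- c("apoe4", "age_group", "n_negative", "n_positive")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("counts table lacks column(s): ",
                         paste(miss, collapse = ", "))
  reps <- rep(seq_len(nrow(counts)), counts$n_negative + counts$n_positive)
  amy <- unlist(lapply(seq_len(nrow(counts)), function(i)
    rep(c("negative", "positive"),
        c(counts$n_negative[i], counts$n_positive[i]))))
  data.frame(apoe4 = counts$apoe4[reps],
             age_group = counts$age_group[reps],
             amyloid = amy, stringsAsFactors = FALSE)
}
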