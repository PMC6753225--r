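#' @keywords internal
"_PACKAGE"

# Canonical function names in reporting order. EM is a single ordinal
# function (levels 0-3) internally; it is expanded to the EM1/EM2/EM3
# indicator triple everywhere results are reported.
FUNCTION_NAMES <- c("ATT", "EM1", "EM2", "EM3", "VF", "CF", "PS")

#' Construct a neuropsychological battery specification
#'
#' A battery specification lists the tests administered and, for each test,
#' the cognitive functions a subject must have at a high level to be expected
#' to perform well: attention (ATT), episodic memory at hierarchical levels
#' EM1-EM3 (immediate recall, intermediate recall with distraction, delayed
#' recall with distractors; level 3 implies levels 1 and 2), verbal fluency
#' (VF), cognitive flexibility (CF), and perceptual motor speed (PS).
#'
#' Episodic memory demands must be contiguous: a test requiring EM2 also
#' requires EM1, so the set of EM levels listed for a test must be
#' \code{EM1, ..., EMk} for some k. Non-contiguous EM requirements are
#' rejected.
#'
#' @param tests a list; each element is a list with fields \code{name}
#'   (unique string), \code{functions} (character vector of required
#'   functions among ATT, EM1, EM2, EM3, VF, CF, PS; at least one),
#'   \code{orientation} (\code{"higher"} or \code{"lower"}, whether larger
#'   raw scores indicate better performance), and optionally
#'   \code{response} (\code{"quartile"} or \code{"timed"}, default
#'   \code{"quartile"}) and \code{label} (free-text description).
#' @param name optional battery name.
#' @return an object of class \code{"battery"}: a list with a \code{tests}
#'   data frame (columns \code{name}, \code{label}, \code{att}, \code{em},
#'   \code{vf}, \code{cf}, \code{ps}, \code{response}, \code{orientation};
#'   \code{em} is the minimum EM level required, 0 if none) in canonical
#'   test order.
#' @examples
#' b <- battery(list(
#'   list(name = "recall", functions = c("ATT", "EM1"), orientation = "higher"),
#'   list(name = "trails", functions = c("ATT", "PS"), orientation = "lower",
#'        response = "timed")))
#' b
#' @export
battery <- function(tests, name = NULL) {
  if (!is.list(tests) || length(tests) == 0L)
    stop("'tests' must be a non-empty list of test specifications")
  rows <- lapply(seq_along(tests), function(i) {
    t <- tests[[i]]
    if (is.null(t$name) || !nzchar(t$name))
      stop("test ", i, ": missing 'name'")
    fns <- t$functions
    if (is.null(fns) || length(fns) == 0L)
      stop("test '", t$name, "': at least one required function must be listed")
    bad <- setdiff(fns, FUNCTION_NAMES)
    if (length(bad))
      stop("test '", t$name, "': unknown function name(s): ",
           paste(bad, collapse = ", "))
    em_levels <- sort(as.integer(sub("^EM", "", grep("^EM[123]$", fns, value = TRUE))))
    em <- if (length(em_levels)) max(em_levels) else 0L
    if (length(em_levels) && !identical(em_levels, seq_len(em)))
      stop("test '", t$name, "': episodic memory requirement must be ",
           "contiguous from EM1 (got EM", paste(em_levels, collapse = ", EM"),
           "); a test requiring EM", em, " also requires all lower levels")
    orientation <- t$orientation
    if (is.null(orientation) || !orientation %in% c("higher", "lower"))
      stop("test '", t$name, "': 'orientation' must be \"higher\" or \"lower\"")
    response <- if (is.null(t$response)) "quartile" else t$response
    if (!response %in% c("quartile", "timed"))
      stop("test '", t$name, "': 'response' must be \"quartile\" or \"timed\"")
    data.frame(name = t$name,
               label = if (is.null(t$label)) t$name else t$label,
               att = as.integer("ATT" %in% fns),
               em = em,
               vf = as.integer("VF" %in% fns),
               cf = as.integer("CF" %in% fns),
               ps = as.integer("PS" %in% fns),
               response = response,
               orientation = orientation,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (anyDuplicated(tab$name))
    stop("duplicate test name(s): ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  structure(list(name = name, tests = tab), class = "battery")
}

#' Read a battery specification from a YAML or JSON file
#'
#' The file must contain a top-level \code{tests} list whose entries follow
#' the schema of \code{\link{battery}}, and may carry a top-level
#' \code{battery} name. Files ending in \code{.json} are parsed as JSON,
#' anything else as YAML (JSON being a YAML subset, either parser accepts
#' the bundled fixtures).
#'
#' @param path path to the specification file.
#' @return a \code{\link{battery}} object.
#' @seealso \code{\link{adni2_battery}}, \code{\link{aibl_battery}} for the
#'   two bundled panels.
#' @export
read_battery <- function(path) {
  if (!file.exists(path)) stop("battery spec file not found: ", path)
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(spec$tests))
    stop("battery spec '", path, "' has no 'tests' entry")
  spec$tests <- lapply(spec$tests, function(t) {
    t$functions <- unlist(t$functions)
    t
  })
  battery(spec$tests, name = spec$battery)
}

#' Bundled battery panels
#'
#' The two screening panels used throughout the package documentation and
#' tests: the 9-test ADNI2 panel (ADAS delayed recall and word recognition,
#' AVLT lists 6 and B, Boston naming, category fluency, ADAS number
#' cancellation, Trail Making A and B) and the 13-test AIBL panel (CVLT
#' subtests, Boston naming, category fluency and switching, Stroop words and
#' colors, CogState detection, identification, one back, one card learning).
#' Every test in both panels involves attention.
#'
#' @return a \code{\link{battery}} object.
#' @examples
#' adni2_battery()
#' @export
adni2_battery <- function() {
  read_battery(system.file("extdata", "battery_adni2.yaml",
                           package = "posetcog", mustWork = TRUE))
}

#' @rdname adni2_battery
#' @export
aibl_battery <- function() {
  read_battery(system.file("extdata", "battery_aibl.yaml",
                           package = "posetcog", mustWork = TRUE))
}

#' @export
print.battery <- function(x, ...) {
  cat("Battery specification", if (!is.null(x$name)) paste0("'", x$name, "'"),
      "with", nrow(x$tests), "tests\n")
  fn <- apply(x$tests, 1, function(r) {
    fns <- c(if (r[["att"]] == "1") "ATT",
             if (as.integer(r[["em"]]) > 0) paste0("EM", seq_len(as.integer(r[["em"]]))),
             if (r[["vf"]] == "1") "VF",
             if (r[["cf"]] == "1") "CF",
             if (r[["ps"]] == "1") "PS")
    paste(fns, collapse = " ")
  })
  print(data.frame(test = x$tests$name, functions = fn,
                   orientation = x$tests$orientation,
                   row.names = NULL), right = FALSE)
  invisible(x)
}

# Required-function names for one test row (EM collapsed to max level).
battery_requirements <- function(bat) {
  stopifnot(inherits(bat, "battery"))
  bat$tests[, c("att", "em", "vf", "cf", "ps")]
}
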