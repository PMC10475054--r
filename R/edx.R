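# standard atomic weights (Da) for elements seen in EDX of biological samples
.atomic_weights <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
  Ca = 40.078, Fe = 55.845, Zn = 65.38
)

.atomic_weight <- function(element) {
  w <- .atomic_weights[element]
  if (any(is.na(w)))
    stop("unknown element symbol(s): ",
         paste(element[is.na(w)], collapse = ", "))
  unname(w)
}

#' Normalize EDX element abundances to weight percent
#'
#' Two conventions are implemented for turning raw per-element abundances
#' into a percentage profile:
#' * `"as_printed"` -- each abundance is divided by the element's atomic mass
#'   and the results normalized to 100 (the formula as stated in the source
#'   table legend this stage mirrors);
#' * `"conventional"` -- the usual atom-fraction-to-weight conversion: each
#'   abundance is multiplied by the atomic mass before normalizing.
#'
#' The legend wording is chemically ambiguous (dividing by mass converts
#' weight to moles, yet the result is labelled wt%), so both are exposed and
#' the convention used is recorded in the output; no intent is guessed.
#'
#' @param table Data frame with columns `element` (symbols) and `abundance`
#'   (`>= 0`, arbitrary units), or a named numeric vector.
#' @param convention `"as_printed"` (default) or `"conventional"`.
#' @return Object of class `wtpct_profile`: data frame (`element`, `wt_pct`)
#'   whose `wt_pct` sums to 100; attributes `convention` and
#'   `organic_content` (C+O+N percentage).
#' @export
#' @examples
#' normalize_wt_pct(c(C = 50, O = 30, Ca = 20))
normalize_wt_pct <- function(table,
                             convention = c("as_printed", "conventional")) {
  convention <- match.arg(convention)
  mass_one <- FALSE
  if (inherits(table, "wtpct_profile")) {
    # already in wt% space: renormalizing is a fixed point (rescale only)
    convention <- attr(table, "convention")
    table <- data.frame(element = table$element, abundance = table$wt_pct)
    mass_one <- TRUE
  }
  if (is.numeric(table) && !is.null(names(table)))
    table <- data.frame(element = names(table), abundance = unname(table))
  if (!is.data.frame(table) ||
      !all(c("element", "abundance") %in% names(table)))
    stop("`table` needs columns `element` and `abundance`")
  if (any(table$abundance < 0)) stop("abundances must be >= 0")
  if (sum(table$abundance) == 0) stop("all-zero abundance table")
  mass <- if (mass_one) rep(1, nrow(table)) else .atomic_weight(table$element)
  x <- if (convention == "as_printed") table$abundance / mass
  else table$abundance * mass
  out <- data.frame(element = table$element, wt_pct = 100 * x / sum(x),
                    stringsAsFactors = FALSE)
  structure(out, class = c("wtpct_profile", "data.frame"),
            convention = convention,
            organic_content = organic_content(out))
}

#' Organic (C + O + N) content of a weight-percent profile
#'
#' @param profile A `wtpct_profile`, or any data frame with `element` and
#'   `wt_pct` columns; absent elements contribute 0.
#' @return Percentage (sum of C, O and N wt%).
#' @export
organic_content <- function(profile) {
  if (!is.data.frame(profile) ||
      !all(c("element", "wt_pct") %in% names(profile)))
    stop("`profile` needs columns `element` and `wt_pct`")
  sum(profile$wt_pct[profile$element %in% c("C", "O", "N")])
}

#' @export
print.wtpct_profile <- function(x, digits = 2, ...) {
  cat("EDX weight-percent profile (convention: ",
      attr(x, "convention"), ")\n", sep = "")
  print(data.frame(element = x$element,
                   `wt%` = round(x$wt_pct, digits), check.names = FALSE),
        row.names = FALSE)
  cat(sprintf("organic (C+O+N) content: %.2f%%\n", organic_content(x)))
  invisible(x)
}
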