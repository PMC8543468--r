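#' Call uptake/secretion direction from a spent-medium measurement
#'
#' A metabolite significantly above the pure-medium baseline in a
#' condition is being secreted, significantly below it taken up;
#' otherwise the exchange stays unconstrained. Significance versus the
#' medium is decided upstream (the flags are inputs).
#'
#' @param abundance measured abundance in the condition.
#' @param media pure-medium baseline abundance.
#' @param sig logical, significant versus the medium.
#' @return `"uptake"`, `"secretion"` or `"unconstrained"`.
#' @export
call_direction <- function(abundance, media, sig) {
  if (!isTRUE(sig)) return("unconstrained")
  if (abundance > media) "secretion"
  else if (abundance < media) "uptake"
  else "unconstrained"
}

#' Derive exchange-flux constraints from exometabolome measurements
#'
#' For every measured metabolite mapped to an exchange reaction:
#' \itemize{
#' \item a direction call per condition via [call_direction()];
#' \item an absolute magnitude floor `phi * max_uptake_rate(exchange)`
#'   (default 1 percent) in each condition with a direction call, ensuring
#'   a minimum level of uptake/secretion in accordance with the data;
#' \item for metabolites significantly changed between conditions whose
#'   baseline-subtracted deltas share a direction, a relative constraint
#'   on the magnitude ratio `|b - media| / |a - media|` with a deviation
#'   tolerance `tau` (default 50 percent): the interval
#'   `[FC (1 - tau), FC (1 + tau)]`.
#' }
#' Opposite-direction metabolites get floors only (a signed magnitude
#' ratio has no linear encoding); a zero denominator delta likewise skips
#' the ratio. Both cases are logged.
#'
#' @param measurements data.frame with columns `metabolite_id`,
#'   `exchange_id`, `abundance_a`, `abundance_b`, `abundance_media`,
#'   `sig_vs_media_a`, `sig_vs_media_b`, `sig_between`.
#' @param ext an `extended_model`.
#' @param tau relative deviation tolerance on the fold change.
#' @param phi activation fraction of the maximum uptake rate.
#' @param max_uptake_mode `"fva"` (per-exchange optimization, default) or
#'   `"global"` (the model's sentinel default bound).
#' @return object of class `exchange_constraint_set`: data.frame with one
#'   row per constrained exchange (`exchange_id`, `metabolite_id`,
#'   `direction_a`, `direction_b`, `abs_floor_a`, `abs_floor_b`,
#'   `ratio_low`, `ratio_high`) plus attributes `tau`, `phi`, `log`.
#' @export
build_exchange_constraints <- function(measurements, ext, tau = 0.5, phi = 0.01,
                                       max_uptake_mode = c("fva", "global")) {
  max_uptake_mode <- match.arg(max_uptake_mode)
  stopifnot(tau >= 0, phi >= 0)
  req <- c("metabolite_id", "exchange_id", "abundance_a", "abundance_b",
           "abundance_media", "sig_vs_media_a", "sig_vs_media_b", "sig_between")
  missing_cols <- setdiff(req, names(measurements))
  if (length(missing_cols))
    stop(sprintf("measurements lack columns: %s", paste(missing_cols, collapse = ", ")))

  log <- character(0)
  rows <- list()
  for (i in seq_len(nrow(measurements))) {
    m <- measurements[i, ]
    if (!m$exchange_id %in% ext$base$exchange_ids) {
      log <- c(log, sprintf("skipped %s: no exchange reaction %s in model",
                            m$metabolite_id, m$exchange_id))
      next
    }
    dir_a <- call_direction(m$abundance_a, m$abundance_media, m$sig_vs_media_a)
    dir_b <- call_direction(m$abundance_b, m$abundance_media, m$sig_vs_media_b)

    mur <- if (max_uptake_mode == "fva") max_uptake_rate(ext, m$exchange_id)
           else ext$base$default_bound
    floor_a <- if (dir_a == "unconstrained") 0 else phi * mur
    floor_b <- if (dir_b == "unconstrained") 0 else phi * mur

    ratio_low <- NA_real_; ratio_high <- NA_real_
    if (isTRUE(m$sig_between)) {
      if (dir_a == "unconstrained" || dir_b == "unconstrained") {
        log <- c(log, sprintf("%s: significant between conditions but direction undefined in one condition; ratio skipped",
                              m$metabolite_id))
      } else if (dir_a != dir_b) {
        log <- c(log, sprintf("%s: opposite direction calls (%s vs %s); ratio skipped, floors kept",
                              m$metabolite_id, dir_a, dir_b))
      } else {
        den <- abs(m$abundance_a - m$abundance_media)
        num <- abs(m$abundance_b - m$abundance_media)
        if (den <= 0) {
          log <- c(log, sprintf("%s: zero baseline-subtracted delta in condition a; ratio skipped",
                                m$metabolite_id))
        } else {
          fc <- num / den
          ratio_low <- max(0, fc * (1 - tau))
          ratio_high <- fc * (1 + tau)
        }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      exchange_id = m$exchange_id, metabolite_id = m$metabolite_id,
      direction_a = dir_a, direction_b = dir_b,
      abs_floor_a = floor_a, abs_floor_b = floor_b,
      ratio_low = ratio_low, ratio_high = ratio_high,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(exchange_id = character(), metabolite_id = character(),
               direction_a = character(), direction_b = character(),
               abs_floor_a = numeric(), abs_floor_b = numeric(),
               ratio_low = numeric(), ratio_high = numeric())
  structure(out, class = c("exchange_constraint_set", "data.frame"),
            tau = tau, phi = phi, log = log)
}

# translate an exchange_constraint_set into LP rows for one condition
# ("a"/"b") over extended columns; ratio rows couple two conditions and are
# produced by marge() itself.
exchange_condition_constraints <- function(constraints, ext, condition) {
  out <- list()
  if (is.null(constraints) || nrow(constraints) == 0L) return(out)
  dcol <- paste0("direction_", condition)
  fcol <- paste0("abs_floor_", condition)
  for (i in seq_len(nrow(constraints))) {
    dir <- constraints[[dcol]][i]
    if (dir == "unconstrained") next
    ex <- constraints$exchange_id[i]
    fl <- constraints[[fcol]][i]
    if (dir == "uptake") {
      # v <= -floor
      out[[length(out) + 1L]] <- list(weights = stats::setNames(1, ex), dir = "<=", rhs = -fl)
    } else {
      out[[length(out) + 1L]] <- list(weights = stats::setNames(1, ex), dir = ">=", rhs = fl)
    }
  }
  out
}

#' Serialize an exchange constraint set to JSON for audit
#'
#' @param constraints an `exchange_constraint_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_constraints_json <- function(constraints, path) {
  obj <- list(tau = attr(constraints, "tau"), phi = attr(constraints, "phi"),
              log = as.list(attr(constraints, "log")),
              constraints = constraints)
  class(obj$constraints) <- "data.frame"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read an exometabolome measurement table
#'
#' Tab-separated with columns `metabolite_id`, `exchange_id`,
#' `abundance_a`, `abundance_b`, `abundance_media`, `sig_vs_media_a`,
#' `sig_vs_media_b`, `sig_between`.
#'
#' @param path TSV file.
#' @return data.frame of measurements.
#' @export
read_exomet_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (cc in c("sig_vs_media_a", "sig_vs_media_b", "sig_between"))
    if (cc %in% names(df)) df[[cc]] <- as.logical(df[[cc]])
  df
}
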