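#' Lyman-Kutcher-Burman model parameters
#'
#' `td50_gy` is the uniform whole-organ dose giving 50% complication
#' probability, `m` the probit slope, and `n` the volume-effect exponent
#' (n near 0: serial organ driven by the maximum dose; n = 1: parallel
#' organ driven by the mean dose).
#'
#' @param endpoint endpoint name (e.g. "heart_pericarditis").
#' @param td50_gy TD50 in Gy (> 0).
#' @param m probit slope (> 0).
#' @param n volume-effect exponent in (0, 1].
#' @param structure name of the structure mask the endpoint applies to.
#' @return an `lkb_params` list.
#' @export
lkb_params <- function(endpoint, td50_gy, m, n, structure = endpoint) {
  if (td50_gy <= 0) stop("TD50 must be positive")
  if (m <= 0) stop("slope m must be positive")
  if (n <= 0 || n > 1) stop("volume exponent n must be in (0, 1]")
  structure(list(endpoint = endpoint, td50_gy = td50_gy, m = m, n = n,
                 structure = structure),
            class = "lkb_params")
}

#' Default LKB parameter set
#'
#' Reads the packaged parameter file (classical literature defaults for
#' heart pericarditis, lung pneumonitis and esophagus perforation);
#' pass a path to substitute an institution-specific file of the same JSON
#' shape.
#'
#' @param path optional path to a JSON parameter file.
#' @return named list of [lkb_params()], keyed by endpoint.
#' @export
default_lkb_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lkb_defaults.json", package = "sctselect")
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ep <- j$endpoints
  out <- lapply(seq_len(nrow(ep)), function(i)
    lkb_params(ep$endpoint[i], ep$td50_gy[i], ep$m[i], ep$n[i], ep$structure[i]))
  names(out) <- ep$endpoint
  out
}

#' Generalized equivalent uniform dose (Kutcher-Burman effective dose)
#'
#' `Deff = (sum_i v_i d_i^(1/n))^n` over the differential DVH with
#' fractional volumes summing to 1 and bin-centre doses. A power mean: for
#' n = 1 it is the mean dose; as n tends to 0 it approaches the maximum
#' dose.
#'
#' @param x a `dvh_curve` from [compute_dvh()], or a list with fractional
#'   volumes `v` and doses `d`.
#' @param n volume-effect exponent in (0, 1].
#' @return Deff in Gy.
#' @export
geud <- function(x, n) {
  if (n <= 0 || n > 1) stop("volume exponent n must be in (0, 1]")
  df <- if (inherits(x, "dvh_curve")) dvh_differential(x) else x
  if (length(df$v) == 0) stop("empty dose distribution")
  v <- df$v / sum(df$v)
  sum(v * df$d^(1 / n))^n
}

#' LKB normal tissue complication probability
#'
#' `NTCP = Phi((Deff - TD50) / (m TD50))` with Phi the standard normal CDF
#' and Deff the generalized equivalent uniform dose at the endpoint's
#' volume exponent.
#'
#' @param dvh a `dvh_curve` for the endpoint's structure.
#' @param params an [lkb_params()].
#' @return list with `endpoint`, `deff_gy` and `ntcp` (probability in
#'   \[0, 1\]).
#' @export
lkb_ntcp <- function(dvh, params) {
  if (!inherits(params, "lkb_params")) stop("`params` must be lkb_params")
  deff <- geud(dvh, params$n)
  t <- (deff - params$td50_gy) / (params$m * params$td50_gy)
  list(endpoint = params$endpoint, deff_gy = deff, ntcp = pnorm(t))
}

#' NTCP result record
#'
#' @param endpoint endpoint name.
#' @param modality "photon" or "proton".
#' @param ct "sct" or "pct".
#' @param ntcp probability in \[0, 1\].
#' @param deff_gy effective dose (Gy).
#' @return an `ntcp_result` list.
#' @export
ntcp_result <- function(endpoint, modality, ct, ntcp, deff_gy = NA_real_) {
  if (ntcp < 0 || ntcp > 1) stop("NTCP must be a probability in [0, 1]")
  structure(list(endpoint = endpoint, modality = modality, ct = ct,
                 ntcp = ntcp, deff_gy = deff_gy),
            class = "ntcp_result")
}

#' Proton-minus-photon NTCP difference
#'
#' Negative values favor the proton plan (lower complication probability).
#'
#' @param proton,photon [ntcp_result()]s for the same endpoint and CT.
#' @return signed probability difference (proton - photon).
#' @export
delta_ntcp <- function(proton, photon) {
  if (proton$endpoint != photon$endpoint)
    stop("NTCP results are for different endpoints")
  if (proton$ct != photon$ct)
    stop("NTCP results come from different CT sources")
  proton$ntcp - photon$ntcp
}

#' Relevance filter on endpoint-case NTCP values
#'
#' An endpoint-case enters the modality comparison only when its NTCP
#' values exceed the threshold (default 0.05%); below that, the endpoint
#' has a negligible effect on the decision. By default inclusion requires
#' ANY of the four values (2 modalities x 2 CTs) above the threshold, so a
#' paired comparison is never half-excluded; set `rule = "all"` to require
#' all four.
#'
#' @param values data.frame with columns `case`, `endpoint`, `modality`,
#'   `ct` and `ntcp` (probability).
#' @param threshold_pct threshold in percent (default 0.05).
#' @param rule "any" or "all".
#' @return data.frame with one row per (case, endpoint): `max_ntcp_pct`,
#'   `min_ntcp_pct` and logical `included`.
#' @export
relevance_filter <- function(values, threshold_pct = 0.05,
                             rule = c("any", "all")) {
  rule <- match.arg(rule)
  if (threshold_pct < 0) stop("threshold must be non-negative")
  key <- interaction(values$case, values$endpoint, drop = TRUE)
  agg <- do.call(rbind, lapply(split(values, key), function(g) {
    data.frame(case = g$case[1], endpoint = g$endpoint[1],
               max_ntcp_pct = 100 * max(g$ntcp),
               min_ntcp_pct = 100 * min(g$ntcp))
  }))
  agg$included <- if (rule == "any") agg$max_ntcp_pct > threshold_pct
                  else agg$min_ntcp_pct > threshold_pct
  rownames(agg) <- NULL
  agg
}

#' Modality-selection verdict from paired NTCP values
#'
#' Applies the relevance filter, forms the proton-minus-photon NTCP
#' difference per endpoint-case on each CT, checks the sign concordance
#' between the synthetic-CT and planning-CT differences (zero concordant
#' with either sign), and reports the preferred modality (proton iff the
#' difference is negative), the overall trend accuracy, the concordance
#' correlation of the paired differences, and per-endpoint deviation
#' statistics.
#'
#' @param values data.frame with columns `case`, `endpoint`, `modality`
#'   ("photon"/"proton"), `ct` ("sct"/"pct") and `ntcp` (probability).
#' @param threshold_pct relevance threshold in percent.
#' @param rule filter rule, see [relevance_filter()].
#' @return a `modality_report`: `pairs` (per endpoint-case data.frame),
#'   `summary` (trend accuracy %, CCC, counts), `by_endpoint` (mean
#'   absolute and median difference-of-differences, %), `verdicts`
#'   (human-readable), `status`.
#' @export
modality_verdict <- function(values, threshold_pct = 0.05,
                             rule = c("any", "all")) {
  rule <- match.arg(rule)
  need <- c("case", "endpoint", "modality", "ct", "ntcp")
  if (!all(need %in% names(values)))
    stop("values must have columns: ", paste(need, collapse = ", "))
  filt <- relevance_filter(values, threshold_pct, rule)
  key <- interaction(values$case, values$endpoint, drop = TRUE)
  pairs <- do.call(rbind, lapply(split(values, key), function(g) {
    pick <- function(mod, ct) {
      v <- g$ntcp[g$modality == mod & g$ct == ct]
      if (length(v) != 1) stop("need exactly one NTCP per (case, endpoint, modality, ct)")
      v
    }
    d_sct <- pick("proton", "sct") - pick("photon", "sct")
    d_pct <- pick("proton", "pct") - pick("photon", "pct")
    data.frame(case = g$case[1], endpoint = g$endpoint[1],
               delta_sct = d_sct, delta_pct = d_pct,
               delta_diff = d_sct - d_pct,
               concordant = sign(d_sct) == sign(d_pct) | d_sct == 0 | d_pct == 0,
               preferred_sct = if (d_sct < 0) "proton" else if (d_sct > 0) "photon" else "tie",
               preferred_pct = if (d_pct < 0) "proton" else if (d_pct > 0) "photon" else "tie")
  }))
  rownames(pairs) <- NULL
  pairs <- merge(pairs, filt[, c("case", "endpoint", "included")],
                 by = c("case", "endpoint"), sort = TRUE)
  inc <- pairs[pairs$included, , drop = FALSE]
  if (nrow(inc) == 0) {
    return(structure(list(pairs = pairs, summary = list(),
                          by_endpoint = list(), verdicts = character(0),
                          status = "no relevant endpoints"),
                     class = "modality_report"))
  }
  acc <- 100 * sum(inc$concordant) / nrow(inc)
  cc <- if (nrow(inc) >= 2 &&
            !(var(inc$delta_sct) == 0 && var(inc$delta_pct) == 0))
    ccc(inc$delta_sct, inc$delta_pct) else NA_real_
  by_ep <- lapply(split(inc, inc$endpoint), function(g)
    list(n = nrow(g),
         mean_abs_delta_diff_pct = 100 * mean(abs(g$delta_diff)),
         median_delta_diff_pct = 100 * median(g$delta_diff)))
  verdicts <- vapply(split(inc, inc$endpoint), function(g) {
    pref <- names(sort(table(g$preferred_pct), decreasing = TRUE))[1]
    sprintf("%s: %s preferred (%d/%d cases concordant between synthetic and planning CT)",
            g$endpoint[1], pref, sum(g$concordant), nrow(g))
  }, character(1))
  structure(list(pairs = pairs,
                 summary = list(trend_accuracy_pct = acc,
                                ccc = cc,
                                ccc_band = if (is.finite(cc)) ccc_band(max(-1, min(1, cc))) else NA_character_,
                                n_included = nrow(inc),
                                n_excluded = sum(!pairs$included),
                                n_concordant = sum(inc$concordant)),
                 by_endpoint = by_ep, verdicts = unname(verdicts),
                 status = "ok"),
            class = "modality_report")
}

#' @export
print.modality_report <- function(x, ...) {
  if (x$status != "ok") {
    cat("<modality_report>", x$status, "\n")
    return(invisible(x))
  }
  cat(sprintf("<modality_report> %d endpoint-cases included (%d excluded by relevance filter)\n",
              x$summary$n_included, x$summary$n_excluded))
  cat(sprintf("  trend accuracy: %.1f%%  CCC: %s\n", x$summary$trend_accuracy_pct,
              if (is.finite(x$summary$ccc))
                sprintf("%.3f (%s)", x$summary$ccc, x$summary$ccc_band) else "n/a"))
  for (v in x$verdicts) cat(" ", v, "\n")
  invisible(x)
}
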