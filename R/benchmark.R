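#' Score a predictor over a set of targets
#'
#' Runs a predictor on each target and scores it against the reference
#' annotation with [ndo_score], then summarizes mean NDO and standard error
#' separately for single-domain and multidomain targets — the two axes on
#' which boundary predictors trade off (oversmoothing favors single-domain
#' chains, undersmoothing favors multidomain ones).
#'
#' @param targets list; each element a list with `contacts` (a
#'   [contact_list]) and `annotation` (the reference [domain_annotation]),
#'   e.g. as produced by [generate_multidomain_contacts].
#' @param predictor function mapping a `contact_list` to a
#'   `domain_annotation`; default the KDE predictor with its standard
#'   settings.
#' @param variant NDO variant passed to [ndo_score].
#' @return An object of class `benchmark_result`: list with `per_target`
#'   (data.frame: target, L, n_domains_true, n_domains_pred, ndo, error)
#'   and `summary` (data.frame by class: n, mean_ndo, se_ndo, n_failed).
#' @export
run_benchmark <- function(targets,
                          predictor = function(cl) predict_domains_kde(cl),
                          variant = c("balanced", "fraction")) {
  variant <- match.arg(variant)
  if (base::length(targets) == 0L) stop("empty target set")
  rows <- vector("list", base::length(targets))
  for (k in seq_along(targets)) {
    tg <- targets[[k]]
    ndo <- NA_real_; npred <- NA_integer_; err <- NA_character_
    res <- tryCatch({
      pred <- predictor(tg$contacts)
      npred <- n_domains(pred)
      ndo <- ndo_score(tg$annotation, pred, variant = variant)$score
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) err <- res
    rows[[k]] <- data.frame(target = k, L = tg$annotation$length,
                            n_domains_true = n_domains(tg$annotation),
                            n_domains_pred = npred, ndo = ndo,
                            error = err, stringsAsFactors = FALSE)
  }
  per_target <- do.call(rbind, rows)
  cls <- ifelse(per_target$n_domains_true == 1L, "single", "multi")
  summ <- do.call(rbind, lapply(c("single", "multi"), function(g) {
    sel <- per_target[cls == g & !is.na(per_target$ndo), , drop = FALSE]
    data.frame(class = g, n = nrow(sel),
               mean_ndo = if (nrow(sel) > 0) mean(sel$ndo) else NA_real_,
               se_ndo = if (nrow(sel) > 1)
                 stats::sd(sel$ndo) / sqrt(nrow(sel)) else NA_real_,
               n_failed = sum(cls == g & !is.na(per_target$error)))
  }))
  structure(list(per_target = per_target, summary = summ, variant = variant),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("Benchmark over", nrow(x$per_target), "targets (NDO variant:",
      x$variant, ")\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Sweep bandwidth schemes over a benchmark set
#'
#' Runs the KDE predictor under each bandwidth scheme on every target,
#' scores with [ndo_score], and reports the mean NDO on single-domain and
#' multidomain targets per scheme together with the mean predicted domain
#' count. Schemes on the Pareto front — those no other scheme beats on both
#' class means — are flagged.
#'
#' @param targets as for [run_benchmark].
#' @param schemes character vector of bandwidth scheme strings (see
#'   [compute_bandwidth]), e.g. `c("fixed:5", "linear:15", "power:2")`.
#' @param variant NDO variant.
#' @param ... further arguments passed to [predict_domains_kde].
#' @return data.frame with one row per scheme: `scheme`, `mean_ndo_single`,
#'   `mean_ndo_multi`, `mean_domains`, `pareto`.
#' @export
bandwidth_sweep <- function(targets, schemes, variant = "balanced", ...) {
  if (base::length(targets) == 0L) stop("empty target set")
  if (base::length(schemes) == 0L) stop("no schemes given")
  rows <- lapply(schemes, function(sc) {
    bm <- run_benchmark(targets,
                        predictor = function(cl)
                          predict_domains_kde(cl, bandwidth = sc, ...),
                        variant = variant)
    s <- bm$summary
    data.frame(scheme = sc,
               mean_ndo_single = s$mean_ndo[s$class == "single"],
               mean_ndo_multi = s$mean_ndo[s$class == "multi"],
               mean_domains = mean(bm$per_target$n_domains_pred, na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  ms <- out$mean_ndo_single; mm <- out$mean_ndo_multi
  ms[is.na(ms)] <- -Inf; mm[is.na(mm)] <- -Inf
  out$pareto <- vapply(seq_len(nrow(out)), function(k) {
    !any(ms >= ms[k] & mm >= mm[k] & (ms > ms[k] | mm > mm[k]))
  }, logical(1))
  out
}
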