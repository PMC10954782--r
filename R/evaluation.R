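#' Relative performance decrease (RPD)
#'
#' The percentage accuracy loss of a federated model relative to the
#' centralized baseline: `(acc_cl - acc_fl) / acc_cl * 100`. The returned
#' value is rounded to two decimals for reporting; the unrounded value is
#' kept in the `"unrounded"` attribute.
#'
#' @param acc_cl Centralized balanced accuracy (percent, > 0).
#' @param acc_fl Federated balanced accuracy (percent).
#' @return RPD in percent, rounded to 2 decimals, with attribute `unrounded`.
#' @export
rpd <- function(acc_cl, acc_fl) {
  if (any(acc_cl <= 0)) stop("acc_cl must be positive")
  v <- (acc_cl - acc_fl) / acc_cl * 100
  structure(round(v, 2), unrounded = v)
}

#' Run the repeated-splits study protocol
#'
#' For each of `n_splits` split seeds, the balanced matched test set is
#' created once and frozen; a validation set (`val_fraction` of the
#' development set, diagnosis-stratified) is carved out for model selection;
#' then every (scenario, approach) cell is trained `n_repetitions` times
#' (fresh training seeds), selected by validation balanced accuracy, and
#' scored on the frozen test set. Cell results are aggregated as mean and
#' sample (n-1) standard deviation over all split x repetition runs. Secure
#' aggregation is skipped (`NA`) for scenarios with fewer than three clients.
#'
#' @param cohort A `fedalz_cohort`.
#' @param scenario_ids Scenarios to run (see [scenario_spec()]).
#' @param approaches Subset of `c("cl", "fedavg", "secagg")`.
#' @param cfg A [fl_config()] giving the training schedule.
#' @param n_splits,n_repetitions Protocol sizes (the study design is 10 x 5;
#'   scaled-down runs record their sizes in the output).
#' @param test_per_class Frozen test-set size per diagnosis.
#' @param val_fraction Fraction of the development set used for validation.
#' @param master_seed Master seed; split/repetition seeds derive from it.
#' @return A `fedalz_study`: list with `runs` (one row per run), `table`
#'   (per-cell mean and sd), `rpd` (per scenario and federated approach,
#'   computed from the cell means), and the protocol sizes.
#' @export
run_study <- function(cohort, scenario_ids = c("1.1", "5.1"),
                      approaches = c("cl", "fedavg"), cfg = fl_config(),
                      n_splits = 3, n_repetitions = 2, test_per_class = 50,
                      val_fraction = 0.15, master_seed = 1) {
  stopifnot(all(approaches %in% c("cl", "fedavg", "secagg")))
  runs <- data.frame()
  for (s in seq_len(n_splits)) {
    split <- make_split(cohort, test_per_class, seed = derive_seed(master_seed, "split", s))
    test_data <- build_dataset(cohort, split$test_ids)
    dev <- cohort$records[cohort$records$subject_id %in% split$dev_ids, ]
    val_ids <- with_seed(derive_seed(master_seed, "val", s), {
      unlist(lapply(c("AD", "CN"), function(dg) {
        pool <- dev$subject_id[dev$diagnosis == dg]
        pool[sample.int(length(pool), max(1, round(val_fraction * length(pool))))]
      }))
    })
    train_rec <- dev[!dev$subject_id %in% val_ids, ]
    val_data <- build_dataset(cohort, val_ids)
    for (sc in scenario_ids) {
      spec_sc <- scenario_spec(sc)
      for (ap in approaches) {
        if (ap == "secagg" && spec_sc$n_clients < cfg$secagg$min_clients) next
        for (rep_i in seq_len(n_repetitions)) {
          run_seed <- derive_seed(master_seed, "run", s, sc, ap, rep_i)
          ba <- tryCatch({
            if (ap == "cl") {
              res <- run_centralized(build_dataset(cohort, train_rec$subject_id),
                                     cfg, val_data, run_seed)
            } else {
              parts <- partition_cohort(train_rec, spec_sc,
                                        seed = derive_seed(master_seed, "part", s, sc))
              cfg_i <- cfg
              cfg_i$aggregator <- if (ap == "secagg") "secagg" else "fedavg"
              res <- run_session(parts, cohort, cfg_i, val_data, run_seed)
            }
            evaluate_model(res$best_params, test_data)$balanced_accuracy
          }, error = function(e) {
            warning(sprintf("cell (%s, %s, split %d, rep %d) failed: %s",
                            sc, ap, s, rep_i, conditionMessage(e)))
            NA_real_
          })
          runs <- rbind(runs, data.frame(
            scenario = sc, approach = ap, split = s, repetition = rep_i,
            balanced_accuracy = 100 * ba))
        }
      }
    }
  }
  tab <- stats::aggregate(balanced_accuracy ~ scenario + approach, runs,
                          function(v) c(mean = mean(v),
                                        sd = if (length(v) > 1) stats::sd(v) else 0),
                          na.action = stats::na.pass)
  tab <- data.frame(scenario = tab$scenario, approach = tab$approach,
                    mean = tab$balanced_accuracy[, "mean"],
                    sd = tab$balanced_accuracy[, "sd"],
                    incomplete = vapply(split(runs$balanced_accuracy,
                                              paste(runs$scenario, runs$approach)),
                                        anyNA, TRUE)[paste(tab$scenario, tab$approach)])
  rpd_rows <- data.frame()
  for (sc in unique(tab$scenario)) {
    cl_mean <- tab$mean[tab$scenario == sc & tab$approach == "cl"]
    if (!length(cl_mean) || is.na(cl_mean)) next
    for (ap in intersect(c("fedavg", "secagg"), tab$approach[tab$scenario == sc])) {
      fl_mean <- tab$mean[tab$scenario == sc & tab$approach == ap]
      rpd_rows <- rbind(rpd_rows, data.frame(
        scenario = sc, approach = ap, acc_cl = cl_mean, acc_fl = fl_mean,
        rpd = as.numeric(rpd(cl_mean, fl_mean))))
    }
  }
  structure(list(runs = runs, table = tab, rpd = rpd_rows,
                 n_splits = n_splits, n_repetitions = n_repetitions),
            class = "fedalz_study")
}

#' Render study results as accuracy and RPD tables
#'
#' @param study A `fedalz_study`.
#' @return A list with `accuracy` (one row per scenario, columns per
#'   approach, "mean +/- sd" strings, `N/A` for unavailable cells) and `rpd`
#'   (scenario by federated approach). Both are plain data.frames, writable
#'   with [write_tsv_table()].
#' @export
report_study <- function(study) {
  stopifnot(inherits(study, "fedalz_study"))
  tab <- study$table
  scens <- unique(tab$scenario)
  fmt <- function(sc, ap) {
    i <- which(tab$scenario == sc & tab$approach == ap)
    if (!length(i) || is.na(tab$mean[i])) return("N/A")
    if (is.na(tab$sd[i])) sprintf("%.1f", tab$mean[i])
    else sprintf("%.1f ± %.1f", tab$mean[i], tab$sd[i])
  }
  acc <- data.frame(
    scenario = scens,
    n_clients = vapply(scens, function(s) as.integer(scenario_spec(s)$n_clients), 0L),
    cl = vapply(scens, fmt, "", ap = "cl"),
    fedavg = vapply(scens, fmt, "", ap = "fedavg"),
    secagg = vapply(scens, fmt, "", ap = "secagg"))
  rpd_tab <- data.frame(scenario = scens)
  for (ap in c("fedavg", "secagg")) {
    rpd_tab[[paste0("rpd_", ap)]] <- vapply(scens, function(sc) {
      i <- which(study$rpd$scenario == sc & study$rpd$approach == ap)
      if (!length(i)) "N/A" else sprintf("%.2f", study$rpd$rpd[i])
    }, "")
  }
  list(accuracy = acc, rpd = rpd_tab)
}

#' Write a results table as TSV
#'
#' @param table A data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
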