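#' Specification of a heterogeneous client-data scenario
#'
#' The ten scenarios cover five environments: (1) uniform and balanced over 3
#' or 4 clients; (2) size-skewed but diagnosis-balanced; (3) sex-imbalanced;
#' (4) age-imbalanced (age groups split at the development-cohort median);
#' (5) diagnosis non-IID. Exact per-client proportions are configuration
#' defaults chosen to realize each scenario's qualitative description:
#'
#' * `1.1` — 3 clients, each the same number of AD and CN subjects.
#' * `1.2` — as 1.1 over 4 clients.
#' * `2`   — 3 balanced clients holding 60/20/20 percent of the data.
#' * `3.1` — 3 uniform clients: two all-female, one all-male.
#' * `3.2` — mirrored: two all-male, one all-female.
#' * `3.3` — 2 uniform clients: one all-female, one all-male.
#' * `4.1` — 3 uniform clients: two below-median age, one above.
#' * `4.2` — 2 uniform clients: one below-, one above-median age.
#' * `5.1` — 3 uniform single-diagnosis clients: CN, CN, AD.
#' * `5.2` — 2 uniform mixed clients: 75% CN + 25% AD, and the reverse.
#'
#' @param scenario_id One of "1.1", "1.2", "2", "3.1", "3.2", "3.3", "4.1",
#'   "4.2", "5.1", "5.2".
#' @param skew_proportions Per-client data shares for scenario 2.
#' @param minority_fraction Fraction of opposite-diagnosis subjects per client
#'   in scenario 5.2.
#' @return A `fedalz_scenario` with `scenario_id`, `n_clients`, `axis` and the
#'   per-client stratum assignment.
#' @export
scenario_spec <- function(scenario_id, skew_proportions = c(0.6, 0.2, 0.2),
                          minority_fraction = 0.25) {
  scenario_id <- as.character(scenario_id)
  defs <- list(
    "1.1" = list(n = 3, axis = "none"),
    "1.2" = list(n = 4, axis = "none"),
    "2"   = list(n = 3, axis = "size"),
    "3.1" = list(n = 3, axis = "sex", groups = c("F", "F", "M")),
    "3.2" = list(n = 3, axis = "sex", groups = c("M", "M", "F")),
    "3.3" = list(n = 2, axis = "sex", groups = c("F", "M")),
    "4.1" = list(n = 3, axis = "age", groups = c("young", "young", "old")),
    "4.2" = list(n = 2, axis = "age", groups = c("young", "old")),
    "5.1" = list(n = 3, axis = "diagnosis", groups = c("CN", "CN", "AD")),
    "5.2" = list(n = 2, axis = "diagnosis", groups = c("CN", "AD"))
  )
  d <- defs[[scenario_id]]
  if (is.null(d)) stop("unknown scenario_id: ", scenario_id)
  if (scenario_id == "2") {
    stopifnot(length(skew_proportions) == d$n,
              abs(sum(skew_proportions) - 1) < 1e-8)
  }
  stopifnot(minority_fraction > 0, minority_fraction < 0.5)
  structure(list(scenario_id = scenario_id, n_clients = d$n, axis = d$axis,
                 groups = d$groups, skew_proportions = skew_proportions,
                 minority_fraction = minority_fraction),
            class = "fedalz_scenario")
}

# draw n ids from pool without replacement (uses the current RNG state)
take_ids <- function(pool, n) {
  stopifnot(n <= length(pool))
  if (n == 0) return(character(0))
  pool[sample.int(length(pool), n)]
}

#' Partition a development cohort into client datasets
#'
#' Implements the scenario's stratum targets exactly (deterministic counts,
#' largest-remainder rounding where shares are fractional); the assignment of
#' individual subjects within a stratum is uniform-random under the seed.
#' Subjects that cannot be used without violating a stratum target are
#' dropped; the dropped count is recorded in the `dropped` attribute.
#'
#' @param records Development-cohort metadata (data.frame with `subject_id`,
#'   `age`, `sex`, `diagnosis`), e.g. `cohort$records` restricted to a split's
#'   `dev_ids`.
#' @param spec A [scenario_spec()].
#' @param seed Integer seed for the within-stratum assignment.
#' @return A list of `fedalz_partition` objects (one per client: `client_id`,
#'   `subject_ids`), with attributes `scenario_id`, `seed`, `dropped`.
#' @export
partition_cohort <- function(records, spec, seed = 1) {
  stopifnot(inherits(spec, "fedalz_scenario"))
  r <- records
  n_cl <- spec$n_clients
  pools <- list(AD = r$subject_id[r$diagnosis == "AD"],
                CN = r$subject_id[r$diagnosis == "CN"])
  assign <- with_seed(derive_seed(seed, "partition", spec$scenario_id), {
    out <- vector("list", n_cl)
    if (spec$axis %in% c("none", "size")) {
      shares <- if (spec$axis == "size") spec$skew_proportions else rep(1 / n_cl, n_cl)
      m <- min(lengths(pools))
      per_class <- if (spec$axis == "size") {
        largest_remainder(m, shares)
      } else rep(m %/% n_cl, n_cl)
      for (cls in names(pools)) {
        pool <- pools[[cls]]
        for (i in seq_len(n_cl)) {
          got <- take_ids(pool, per_class[i])
          pool <- setdiff(pool, got)
          out[[i]] <- c(out[[i]], got)
        }
      }
    } else if (spec$axis %in% c("sex", "age")) {
      grp <- if (spec$axis == "sex") r$sex else {
        ifelse(r$age <= median(r$age), "young", "old")
      }
      names(grp) <- r$subject_id
      # per-client, per-class quota: uniform client sizes, diagnosis-balanced
      avail <- sapply(unique(spec$groups), function(g) {
        n_g <- sum(spec$groups == g)
        min(sapply(pools, function(p) sum(grp[p] == g))) %/% n_g
      })
      k <- min(avail)
      if (k < 1) stop("infeasible stratum: no subjects left for group ",
                      names(avail)[which.min(avail)])
      for (cls in names(pools)) {
        pool <- pools[[cls]]
        for (i in seq_len(n_cl)) {
          sub <- pool[grp[pool] == spec$groups[i]]
          got <- take_ids(sub, k)
          pool <- setdiff(pool, got)
          out[[i]] <- c(out[[i]], got)
        }
      }
    } else if (spec$axis == "diagnosis" && spec$scenario_id == "5.1") {
      k <- min(length(pools$CN) %/% 2, length(pools$AD))
      if (k < 1) stop("infeasible stratum: need AD and CN subjects")
      pool_cn <- pools$CN
      for (i in seq_len(n_cl)) {
        cls <- spec$groups[i]
        pool <- if (cls == "CN") pool_cn else pools$AD
        got <- take_ids(pool, k)
        if (cls == "CN") pool_cn <- setdiff(pool_cn, got)
        out[[i]] <- got
      }
    } else {  # 5.2: two mixed clients with a minority fraction swapped in
      mf <- spec$minority_fraction
      den <- 1 / mf  # client size must make the minority count integral
      s <- (min(lengths(pools)) %/% den) * den
      if (s < den) stop("infeasible stratum: too few subjects per diagnosis")
      n_min <- as.integer(s * mf)
      pool_ad <- pools$AD; pool_cn <- pools$CN
      for (i in seq_len(n_cl)) {
        major <- spec$groups[i]
        n_maj <- as.integer(s - n_min)
        maj_pool <- if (major == "CN") pool_cn else pool_ad
        min_pool <- if (major == "CN") pool_ad else pool_cn
        got_maj <- take_ids(maj_pool, n_maj)
        got_min <- take_ids(min_pool, n_min)
        if (major == "CN") { pool_cn <- setdiff(pool_cn, got_maj); pool_ad <- setdiff(pool_ad, got_min) }
        else { pool_ad <- setdiff(pool_ad, got_maj); pool_cn <- setdiff(pool_cn, got_min) }
        out[[i]] <- c(got_maj, got_min)
      }
    }
    out
  })
  parts <- lapply(seq_len(n_cl), function(i) {
    structure(list(client_id = i, subject_ids = assign[[i]]),
              class = "fedalz_partition")
  })
  used <- length(unlist(assign))
  attr(parts, "scenario_id") <- spec$scenario_id
  attr(parts, "seed") <- seed
  attr(parts, "dropped") <- nrow(r) - used
  parts
}

#' Per-client composition table
#'
#' @param partitions Output of [partition_cohort()].
#' @param records The metadata the partitions were drawn from.
#' @return A data.frame with one row per client: `client_id`, `n_subjects`,
#'   `n_ad`, `n_cn`, `n_f`, `n_m`, `mean_age`.
#' @export
describe_partitions <- function(partitions, records) {
  if (length(partitions) == 0) stop("empty partition list")
  do.call(rbind, lapply(partitions, function(p) {
    i <- match(p$subject_ids, records$subject_id)
    stopifnot(!anyNA(i))
    data.frame(client_id = p$client_id,
               n_subjects = length(i),
               n_ad = sum(records$diagnosis[i] == "AD"),
               n_cn = sum(records$diagnosis[i] == "CN"),
               n_f = sum(records$sex[i] == "F"),
               n_m = sum(records$sex[i] == "M"),
               mean_age = mean(records$age[i]))
  }))
}

#' Write a partition manifest as CSV
#'
#' @param partitions Output of [partition_cohort()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_partition_csv <- function(partitions, path) {
  df <- do.call(rbind, lapply(partitions, function(p) {
    data.frame(subject_id = p$subject_ids, client_id = p$client_id,
               scenario_id = attr(partitions, "scenario_id"),
               seed = attr(partitions, "seed"), stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
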