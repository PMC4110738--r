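#' The higher-importance additional-protein subset
#'
#' Names of the 14 additional proteins proposed to contribute more to the
#' pheromone pathway than the remainder; in the split experiment these are
#' given the elevated concentration range while the other 27 stay at the
#' base range.
#'
#' @return character vector of 14 protein names.
#' @export
sigma_proteins <- function() {
  c("CBK1", "PTC1", "DSE1", "SPA2", "SPH1", "MPT5", "KDX1", "HYM1",
    "DIB1", "YHR131C", "BDF2", "SAS10", "RBS1", "YJR003C")
}

#' Concentration sweep plan
#'
#' Defines the grid of initial concentrations for a sweep.  The ten core
#' component proteins (the psi set: alpha-factor, the Ste2 receptor, Ste20,
#' Ste5, Fus3, Akr1, Ste11, Ste7, Ste50, Bem1) always move together through
#' `psi_range`.  The additional proteins form the group axis:
#'
#' * `exp1`: all additional proteins move together through 100..150;
#' * `exp2`: as `exp1` but through 151..200;
#' * `exp3`: the roster splits into sigma (14 higher-importance proteins,
#'   151..200) and varsigma (the remaining 27, 100..150).  The two ranges
#'   have 50 and 51 members, so the group axis runs over 51 joint levels
#'   with sigma's top value repeated at the last level; thresholds (`y`)
#'   are read on the sigma value.
#'
#' @param experiment one of `"exp1"`, `"exp2"`, `"exp3"`.
#' @param psi_range integer vector of psi concentrations.
#' @param lambda_range group range for `exp1`/`exp2` (defaults 100:150 and
#'   151:200 respectively).
#' @param sigma_range,varsigma_range ranges for the `exp3` split.
#' @param sigma_members names of the sigma proteins.
#' @return list of class `concentration_plan`.
#' @export
concentration_plan <- function(experiment = c("exp1", "exp2", "exp3"),
                               psi_range = 300:400,
                               lambda_range = NULL,
                               sigma_range = 151:200,
                               varsigma_range = 100:150,
                               sigma_members = sigma_proteins()) {
  experiment <- match.arg(experiment)
  psi_range <- as.integer(psi_range)
  if (experiment %in% c("exp1", "exp2")) {
    if (is.null(lambda_range))
      lambda_range <- if (experiment == "exp1") 100:150 else 151:200
    plan <- list(experiment = experiment, psi_values = psi_range,
                 group_values = as.integer(lambda_range),
                 group_a = list(which = "lambda",
                                values = as.integer(lambda_range)),
                 group_b = NULL, sigma_members = NULL)
  } else {
    sigma_range <- as.integer(sigma_range)
    varsigma_range <- as.integer(varsigma_range)
    n_levels <- max(length(sigma_range), length(varsigma_range))
    sig <- sigma_range[pmin(seq_len(n_levels), length(sigma_range))]
    var <- varsigma_range[pmin(seq_len(n_levels), length(varsigma_range))]
    plan <- list(experiment = experiment, psi_values = psi_range,
                 group_values = sig,
                 group_a = list(which = "sigma", values = sig),
                 group_b = list(which = "varsigma", values = var),
                 sigma_members = sigma_members)
  }
  structure(plan, class = "concentration_plan")
}

#' @export
print.response_profile <- function(x, ...) {
  if (x$kind == "negative") {
    cat("<response_profile> negative")
  } else {
    cat(sprintf("<response_profile> %s (x = %d, y = %d)", x$kind, x$x, x$y))
  }
  cat(sprintf("; monotone=%s, %d budget-flagged cells\n", x$monotone,
              x$n_budget))
  invisible(x)
}

#' @export
print.concentration_plan <- function(x, ...) {
  cat(sprintf("<concentration_plan> %s: psi %d..%d x %d group levels\n",
              x$experiment, min(x$psi_values), max(x$psi_values),
              length(x$group_values)))
  invisible(x)
}

# place identifier sets for a configured pathway net
tagged_places <- function(net, tag) {
  names(Filter(function(x) tag %in% x, net$place_tags))
}

plan_groups <- function(net, plan, roster) {
  additional <- tagged_places(net, "additional")
  if (plan$experiment == "exp3") {
    sig_ids <- roster$id[toupper(roster$name) %in% toupper(plan$sigma_members)]
    if (length(sig_ids) != length(plan$sigma_members))
      stop("sigma membership does not resolve against the roster")
    list(a = intersect(additional, sig_ids),
         b = setdiff(additional, sig_ids))
  } else {
    list(a = additional, b = character())
  }
}

#' Initial marking for one grid cell
#'
#' All psi places are set to `psi_value`; every additional-protein place is
#' set to its group's value (all members of a group share one value); every
#' other place keeps the model's technical-presence tokens (zero elsewhere).
#'
#' @param config a `network_config` built from the pathway model.
#' @param plan a [concentration_plan].
#' @param psi_value psi concentration, within the plan's range.
#' @param group_values named integer vector: `c(lambda = v)` for
#'   `exp1`/`exp2` plans, `c(sigma = v, varsigma = w)` for `exp3` plans.
#' @param roster the additional-protein roster (packaged default).
#' @return a [marking] over the configuration's net.
#' @export
initial_marking <- function(config, plan, psi_value, group_values,
                            roster = load_protein_roster()) {
  net <- config$net
  psi_value <- as.integer(psi_value)
  if (!psi_value %in% plan$psi_values)
    stop("psi value ", psi_value, " outside the plan's range")
  groups <- plan_groups(net, plan, roster)
  m <- config$m0 %||% marking(net)
  m <- check_marking(net, m)
  m[tagged_places(net, "psi")] <- psi_value
  if (plan$experiment == "exp3") {
    if (!all(c("sigma", "varsigma") %in% names(group_values)))
      stop("exp3 plans need group_values = c(sigma = ..., varsigma = ...)")
    if (!group_values[["sigma"]] %in% plan$group_a$values ||
        !group_values[["varsigma"]] %in% plan$group_b$values)
      stop("group value outside the plan's range")
    m[groups$a] <- as.integer(group_values[["sigma"]])
    m[groups$b] <- as.integer(group_values[["varsigma"]])
  } else {
    v <- as.integer(group_values[[1L]])
    if (!v %in% plan$group_values)
      stop("group value ", v, " outside the plan's range")
    m[groups$a] <- v
  }
  class(m) <- "marking"
  m
}

#' Simulate one response
#'
#' Runs the configured network from a marking and reports whether the
#' Ste12-producing target transition fired.  Runs that exhaust the firing
#' budget are counted negative and carry attribute `budget = TRUE`.
#'
#' @param config a `network_config`.
#' @param m an initial [marking] (e.g. from [initial_marking()]).
#' @param target target transition; `"t23"` (release of Ste12 from the
#'   repression complex) by default.
#' @param policy a [firing_policy].
#' @return logical scalar with attribute `budget`.
#' @export
simulate_response <- function(config, m, target = "t23",
                              policy = firing_policy()) {
  res <- run(config$net, m, policy, target)
  structure(res$target_fired,
            budget = res$termination_reason == "step_budget")
}

#' Sweep a concentration grid
#'
#' Evaluates the response at every (psi value, group level) cell of the
#' plan's grid.
#'
#' @inheritParams simulate_response
#' @param plan a [concentration_plan].
#' @param roster additional-protein roster (packaged default).
#' @return list of class `sweep_result`: `fired` and `budget` logical
#'   matrices (psi values x group levels), `psi_values`, `group_values`,
#'   `plan`.
#' @export
sweep <- function(config, plan, target = "t23", policy = firing_policy(),
                  roster = load_protein_roster()) {
  net <- config$net
  cn <- compile_net(net)
  base <- config$m0 %||% marking(net)
  base <- as.integer(check_marking(net, base)[cn$places])
  pidx <- setNames(seq_along(cn$places), cn$places)
  groups <- plan_groups(net, plan, roster)
  ga_vals <- plan$group_a$values
  gb_vals <- if (is.null(plan$group_b)) integer() else plan$group_b$values
  res <- cpp_sweep(cn, base,
                   unname(pidx[tagged_places(net, "psi")]),
                   plan$psi_values,
                   unname(pidx[groups$a]), ga_vals,
                   unname(pidx[groups$b]), gb_vals,
                   which(cn$transitions == check_transition(net, target)) - 1L,
                   policy$max_steps)
  dimnames(res$fired) <- dimnames(res$budget) <-
    list(plan$psi_values, plan$group_values)
  structure(list(fired = res$fired, budget = res$budget,
                 psi_values = plan$psi_values,
                 group_values = plan$group_values, plan = plan),
            class = "sweep_result")
}

#' Classify a sweep into a response profile
#'
#' A network is `negative` if no grid cell fired.  Otherwise `x` is the
#' minimal psi value with any positive cell and `y` the group value of the
#' first positive group level at that `x`.  The response is `type_a` when
#' that level is the grid's group minimum (the response is governed by the
#' core proteins alone) and `type_b` otherwise (an additional-protein
#' threshold is required too).  A monotonicity flag records whether the grid
#' is upward-closed in both coordinates (positive cells imply positive
#' cells at all larger psi and group levels).
#'
#' @param sw a `sweep_result`.
#' @return list of class `response_profile`: `kind` (`"negative"`,
#'   `"type_a"`, `"type_b"`), `x`, `y`, `y_level`, `monotone`, `n_budget`.
#' @export
classify_profile <- function(sw) {
  g <- sw$fired
  n_budget <- sum(sw$budget)
  if (!any(g)) {
    return(structure(list(kind = "negative", x = NA_integer_,
                          y = NA_integer_, y_level = NA_integer_,
                          monotone = TRUE, n_budget = n_budget),
                     class = "response_profile"))
  }
  i <- which(rowSums(g) > 0L)[1L]
  j <- which(g[i, ])[1L]
  up_closed <- function(m) {
    # positive implies positive to the right and below-to-larger indices
    rows_ok <- all(apply(m, 2L, function(col) !is.unsorted(col)))
    cols_ok <- all(apply(m, 1L, function(row) !is.unsorted(row)))
    rows_ok && cols_ok
  }
  structure(list(
    kind = if (j == 1L) "type_a" else "type_b",
    x = sw$psi_values[i],
    y = sw$group_values[j],
    y_level = unname(j),
    monotone = up_closed(g * 1L),
    n_budget = n_budget), class = "response_profile")
}

#' Generate one randomized network from a pathway model
#'
#' @param model a `pathway_model` from [build_pathway_model()].
#' @param seed integer seed for the weight draw.
#' @return a `network_config` carrying the model's technical-presence
#'   marking.
#' @export
generate_network <- function(model, seed) {
  config <- assign_weights(model$net, seed)
  config$m0 <- marking(model$net, model$m0[as.integer(model$m0) > 0L])
  config
}

profile_row <- function(id, seed, prof) {
  data.frame(network_id = id, seed = seed, kind = prof$kind,
             x = prof$x, y = prof$y, y_level = prof$y_level,
             monotone = prof$monotone, n_budget = prof$n_budget,
             positive = prof$kind != "negative",
             stringsAsFactors = FALSE)
}

new_report <- function(experiment, profiles, weights, plan, target, policy,
                       master_seed, model) {
  structure(list(experiment = experiment, profiles = profiles,
                 weights = weights, plan = plan, target = target,
                 policy = policy, master_seed = master_seed, model = model),
            class = "ensemble_report")
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat(sprintf("<ensemble_report> %s: %d networks, %d positive\n",
              x$experiment, nrow(x$profiles), sum(x$profiles$positive)))
  invisible(x)
}

#' Positive / negative network ids of a report
#' @param report an `ensemble_report`.
#' @return character vector of network ids.
#' @export
positives <- function(report) {
  report$profiles$network_id[report$profiles$positive]
}

#' @rdname positives
#' @export
negatives <- function(report) {
  report$profiles$network_id[!report$profiles$positive]
}

#' Ensemble experiment over randomized networks
#'
#' `experiment1()` generates `n_networks` weight configurations (per-network
#' seeds derived from `master_seed`), sweeps each over the base-range grid
#' (psi 300..400 by additional proteins 100..150) and partitions the
#' ensemble into positive and negative responders.
#'
#' @param n_networks ensemble size.
#' @param master_seed integer master seed; per-network seeds are derived
#'   from it so any subset replays identically.
#' @param plan a [concentration_plan] (defaults to the experiment's own).
#' @param model a `pathway_model` (packaged default).
#' @param target target transition identifier.
#' @param policy a [firing_policy].
#' @param progress print a line every 50 networks.
#' @return an `ensemble_report`: per-network `profiles`, the `weights`
#'   matrix (network x edge), and full provenance for exact replay.
#' @export
experiment1 <- function(n_networks, master_seed,
                        plan = concentration_plan("exp1"),
                        model = build_pathway_model(), target = "t23",
                        policy = firing_policy(), progress = FALSE) {
  stopifnot(n_networks >= 0L)
  ids <- sprintf("net%05d", seq_len(n_networks))
  rows <- vector("list", n_networks)
  wmat <- NULL
  for (i in seq_len(n_networks)) {
    seed_i <- derive_seed(master_seed, 1L, i)
    config <- generate_network(model, seed_i)
    if (is.null(wmat))
      wmat <- matrix(NA_integer_, n_networks, length(config$weights),
                     dimnames = list(ids, names(config$weights)))
    wmat[i, ] <- config$weights
    prof <- classify_profile(sweep(config, plan, target, policy,
                                   roster = model$roster))
    rows[[i]] <- profile_row(ids[i], seed_i, prof)
    if (progress && i %% 50L == 0L)
      message("experiment1: ", i, "/", n_networks)
  }
  profiles <- if (n_networks == 0L) empty_profiles() else
    do.call(rbind, rows)
  if (is.null(wmat))
    wmat <- matrix(integer(), 0L, 0L,
                   dimnames = list(character(), character()))
  new_report("exp1", profiles, wmat, plan, target, policy, master_seed, model)
}

empty_profiles <- function() {
  data.frame(network_id = character(), seed = integer(), kind = character(),
             x = integer(), y = integer(), y_level = integer(),
             monotone = logical(), n_budget = integer(),
             positive = logical(), stringsAsFactors = FALSE)
}

#' Re-sweep the negative networks at the elevated additional-protein range
#'
#' `experiment2()` takes the networks that responded negatively in a base
#' ensemble report and re-runs the identical weight configurations with the
#' additional proteins at 151..200, asking whether a higher accessory
#' protein supply can turn the response positive.
#'
#' @param report1 the `ensemble_report` of [experiment1()].
#' @param plan a [concentration_plan] with the elevated range.
#' @inheritParams experiment1
#' @return an `ensemble_report` over the previously negative networks.
#' @export
experiment2 <- function(report1, plan = concentration_plan("exp2"),
                        target = report1$target, policy = report1$policy,
                        progress = FALSE) {
  neg <- negatives(report1)
  model <- report1$model
  rows <- vector("list", length(neg))
  for (i in seq_along(neg)) {
    id <- neg[i]
    if (!id %in% rownames(report1$weights))
      stop("no persisted configuration for network ", id)
    seed_i <- report1$profiles$seed[report1$profiles$network_id == id]
    config <- set_weights(model$net, report1$weights[id, ], seed_i)
    config$m0 <- marking(model$net, model$m0[as.integer(model$m0) > 0L])
    prof <- classify_profile(sweep(config, plan, target, policy,
                                   roster = model$roster))
    rows[[i]] <- profile_row(id, seed_i, prof)
    if (progress && i %% 50L == 0L)
      message("experiment2: ", i, "/", length(neg))
  }
  profiles <- if (length(neg) == 0L) empty_profiles() else do.call(rbind, rows)
  new_report("exp2", profiles,
             report1$weights[neg, , drop = FALSE], plan, target, policy,
             report1$master_seed, model)
}

#' Split-range experiment over the newly positive networks
#'
#' `experiment3()` takes the networks that turned positive at the elevated
#' range and re-sweeps them with the additional proteins split: the 14
#' sigma proteins at 151..200, the remaining 27 at 100..150.  Each network
#' is classed `CS` (positive with the same `(x, y)` combination as before,
#' `y` now read on the sigma value), `CD` (positive with a different
#' combination) or `CN` (negative).
#'
#' @param report2 the `ensemble_report` of [experiment2()].
#' @param plan an `exp3` [concentration_plan].
#' @inheritParams experiment1
#' @return an `ensemble_report` whose profiles carry a `class` column.
#' @export
experiment3 <- function(report2, plan = concentration_plan("exp3"),
                        target = report2$target, policy = report2$policy,
                        progress = FALSE) {
  pos <- positives(report2)
  model <- report2$model
  rows <- vector("list", length(pos))
  for (i in seq_along(pos)) {
    id <- pos[i]
    if (!id %in% rownames(report2$weights))
      stop("no persisted configuration for network ", id)
    seed_i <- report2$profiles$seed[report2$profiles$network_id == id]
    config <- set_weights(model$net, report2$weights[id, ], seed_i)
    config$m0 <- marking(model$net, model$m0[as.integer(model$m0) > 0L])
    prof <- classify_profile(sweep(config, plan, target, policy,
                                   roster = model$roster))
    row <- profile_row(id, seed_i, prof)
    old <- report2$profiles[report2$profiles$network_id == id, ]
    row$class <- if (prof$kind == "negative") "CN"
      else if (!is.na(old$x) && prof$x == old$x && prof$y == old$y) "CS"
      else "CD"
    rows[[i]] <- row
    if (progress && i %% 50L == 0L)
      message("experiment3: ", i, "/", length(pos))
  }
  profiles <- if (length(pos) == 0L) {
    p <- empty_profiles(); p$class <- character(); p
  } else do.call(rbind, rows)
  new_report("exp3", profiles,
             report2$weights[pos, , drop = FALSE], plan, target, policy,
             report2$master_seed, model)
}
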