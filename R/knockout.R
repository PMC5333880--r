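#' Knockout units from an MCT partition
#'
#' Since the transitions of an MCT set always appear in exactly the same
#' invariant supports, disabling any member has the same structural impact as
#' disabling the whole set; a knockout unit is therefore either a non-trivial
#' MCT set or a single trivial transition.
#'
#' @param mct an `mct_partition` (see [compute_mct_sets()])
#' @return named list of character vectors of transition ids
#' @export
knock_units <- function(mct) {
  stopifnot(inherits(mct, "mct_partition"))
  mct$sets
}

#' Structural knockout table
#'
#' For every knockout unit, the percentage of t-invariants whose support
#' intersects the unit: the fraction of stationary subprocesses that would be
#' lost were the unit's transitions disabled. This ranks functional units by
#' structural impact using the invariants only (no simulation).
#'
#' @param support binary support matrix (rows = invariants, columns =
#'   transitions)
#' @param units named list of transition-id sets (e.g. from [knock_units()]);
#'   a character vector is treated as one single-transition unit per element
#' @return data frame with columns `unit`, `affected_percent` (2 decimals)
#'   and `affected_invariants` (comma-separated invariant row labels), sorted
#'   by decreasing percentage, ties broken by unit name
#' @export
structural_knockout_table <- function(support, units) {
  support <- as.matrix(support) != 0
  if (is.character(units)) units <- stats::setNames(as.list(units), units)
  if (is.null(names(units)) || any(names(units) == ""))
    stop("`units` must be a named list")
  tl <- colnames(support)
  rl <- rownames(support)
  if (is.null(rl)) rl <- paste0("x", seq_len(nrow(support)))
  rows <- lapply(names(units), function(nm) {
    u <- units[[nm]]
    unknown <- setdiff(u, tl)
    if (length(unknown))
      stop("unit ", nm, " references unknown transitions: ",
           paste(unknown, collapse = ", "))
    hit <- rowSums(support[, u, drop = FALSE]) > 0
    data.frame(unit = nm,
               affected_percent = round(100 * sum(hit) / nrow(support), 2),
               affected_invariants = paste(rl[hit], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$affected_percent, out$unit), ]
  rownames(out) <- NULL
  out
}

#' Simulation parameters for the stochastic token game
#'
#' @param steps number of token-game steps per repetition (default 10,000,
#'   the full published scale)
#' @param repetitions number of independent repetitions (default 4,000)
#' @param firing_probability chance that each enabled transition "wills" to
#'   fire in a step (default 0.5)
#' @param seed master seed; each repetition derives its own seed from it, so
#'   repetitions are independent of execution order
#' @param disabled transition ids forced permanently inactive (OFFLINE)
#' @param mode conflict-resolution mode within a step: `"random-order"`
#'   (willing transitions fire sequentially in uniformly random order,
#'   enabledness re-checked before each individual firing, production
#'   immediately available) or `"maximal"` (a maximal concurrently-firable
#'   subset of the willing transitions is chosen greedily in random order
#'   against the step-start marking, production applied at the end of the
#'   step)
#' @return list of class `simulation_params`
#' @export
simulation_params <- function(steps = 10000, repetitions = 4000,
                              firing_probability = 0.5, seed = 1,
                              disabled = character(),
                              mode = c("random-order", "maximal")) {
  stopifnot(steps >= 1, repetitions >= 1,
            firing_probability > 0, firing_probability <= 1)
  structure(list(steps = as.integer(steps),
                 repetitions = as.integer(repetitions),
                 firing_probability = firing_probability,
                 seed = as.integer(seed),
                 disabled = as.character(disabled),
                 mode = match.arg(mode)),
            class = "simulation_params")
}

#' Stochastic token-game simulation
#'
#' Repeats the token game from the net's initial marking: in every step each
#' enabled, non-disabled transition independently wills to fire with the
#' given probability, and the willing transitions are resolved according to
#' the conflict mode (see [simulation_params()]), so token counts can never
#' go negative. The marking is sampled at the end of every step.
#'
#' Per transition the package reports the average firing chance (fraction of
#' steps in which it fired, averaged over repetitions) and its standard
#' deviation across repetitions; per place the average token count over steps
#' and its standard deviation across repetitions. Statuses: `OFFLINE` exactly
#' for the manually disabled transitions, `KNOCKOUT` for never-disabled
#' transitions that fired zero times in all repetitions (starved of tokens),
#' `ACTIVE` otherwise.
#'
#' @param net a `petri_net` with its initial marking
#' @param params a `simulation_params` object
#' @return object of class `simulation_package`: list with data frames
#'   `transitions` (id, status, mean_firing, sd_firing) and `places`
#'   (id, mean_tokens, sd_tokens), plus the `params` used
#' @export
run_simulation <- function(net, params = simulation_params()) {
  stopifnot(inherits(net, "petri_net"), inherits(params, "simulation_params"))
  tl <- transition_ids(net); pl <- place_ids(net)
  unknown <- setdiff(params$disabled, tl)
  if (length(unknown)) stop("disabled lists unknown transitions: ",
                            paste(unknown, collapse = ", "))
  fl <- flow_matrices(net)
  con <- fl$consumption; pro <- fl$production
  m <- length(tl)
  off <- tl %in% params$disabled
  p <- params$firing_probability
  steps <- params$steps

  fire_frac <- matrix(0, params$repetitions, m)      # per-rep firing fractions
  token_mean <- matrix(0, params$repetitions, length(pl))

  for (r in seq_len(params$repetitions)) {
    set.seed((params$seed + r) %% .Machine$integer.max)
    mk <- net$marking
    fired <- integer(m)
    tok <- numeric(length(pl))
    for (s in seq_len(steps)) {
      enabled <- colSums(con > mk) == 0L & !off
      willing <- which(enabled & stats::runif(m) < p)
      if (length(willing)) {
        ord <- if (length(willing) == 1L) willing else sample(willing)
        if (params$mode == "random-order") {
          for (j in ord) {
            if (all(con[, j] <= mk)) {
              mk <- mk - con[, j] + pro[, j]
              fired[j] <- fired[j] + 1L
            }
          }
        } else {                         # maximal concurrent step
          avail <- mk
          chosen <- integer()
          for (j in ord) {
            if (all(con[, j] <= avail)) {
              avail <- avail - con[, j]
              chosen <- c(chosen, j)
            }
          }
          if (length(chosen)) {
            mk <- avail + rowSums(pro[, chosen, drop = FALSE])
            fired[chosen] <- fired[chosen] + 1L
          }
        }
      }
      tok <- tok + mk
    }
    fire_frac[r, ] <- fired / steps
    token_mean[r, ] <- tok / steps
  }

  status <- ifelse(off, "OFFLINE",
                   ifelse(colSums(fire_frac) == 0, "KNOCKOUT", "ACTIVE"))
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  structure(list(
    transitions = data.frame(id = tl, status = status,
                             mean_firing = colMeans(fire_frac),
                             sd_firing = apply(fire_frac, 2, sd0),
                             stringsAsFactors = FALSE),
    places = data.frame(id = pl,
                        mean_tokens = colMeans(token_mean),
                        sd_tokens = apply(token_mean, 2, sd0),
                        stringsAsFactors = FALSE),
    params = params),
    class = "simulation_package")
}

#' @export
print.simulation_package <- function(x, ...) {
  cat(sprintf("<simulation_package> %d transitions (%d OFFLINE, %d KNOCKOUT), %d places; %d steps x %d reps\n",
              nrow(x$transitions), sum(x$transitions$status == "OFFLINE"),
              sum(x$transitions$status == "KNOCKOUT"), nrow(x$places),
              x$params$steps, x$params$repetitions))
  invisible(x)
}

#' Compare a knockout simulation against a reference
#'
#' Tabulates, per transition, the average firing chance in the reference run,
#' in the knockout run, and their difference (knockout minus reference).
#' Transitions that are OFFLINE or KNOCKOUT in the knockout run are labeled
#' by status and get `NA` instead of a numeric difference.
#'
#' @param reference `simulation_package` of the undisturbed net
#' @param knockout `simulation_package` with some transitions disabled
#' @return data frame with columns `transition`, `status`, `reference`,
#'   `knockout`, `difference`
#' @export
compare_simulation_packages <- function(reference, knockout) {
  stopifnot(inherits(reference, "simulation_package"),
            inherits(knockout, "simulation_package"))
  if (!identical(reference$transitions$id, knockout$transitions$id))
    stop("simulation packages describe different transition sets")
  status <- knockout$transitions$status
  diff <- knockout$transitions$mean_firing - reference$transitions$mean_firing
  diff[status != "ACTIVE"] <- NA_real_
  data.frame(transition = reference$transitions$id,
             status = status,
             reference = reference$transitions$mean_firing,
             knockout = knockout$transitions$mean_firing,
             difference = diff,
             stringsAsFactors = FALSE)
}
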