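#' Mutation rate at a given age
#'
#' Evaluates the exponentially interpolated per-replication mtDNA mutation
#' probability `mu(t) = muStart * (muEnd/muStart)^(t/tEnd)`; times beyond
#' `tEnd` extrapolate the same law.
#'
#' @param t age in years (vectorised, must be non-negative).
#' @param schedule a [MutationRateSchedule-class].
#' @return Mutation probability per mtDNA replication event.
#' @examples
#' mutationRateAt(c(0, 40, 80), mutationRateSchedule())
#' @export
mutationRateAt <- function(t, schedule = mutationRateSchedule()) {
  stopifnot(is(schedule, "MutationRateSchedule"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be non-negative and finite")
  schedule@muStart * (schedule@muEnd / schedule@muStart)^(t / schedule@tEnd)
}

#' Replicate the mtDNA pool of a dividing cell
#'
#' Doubles the molecule pool ahead of cell division. Under the default
#' `"doubling"` scheme every molecule is replicated exactly once; each newly
#' synthesised copy of a wild-type template becomes a fresh mutant lineage
#' with probability `mu`, while copies of mutant templates inherit their
#' template's lineage (no back-mutation). The `"resample"` scheme instead
#' draws all 2M molecules with replacement from the template pool, a more
#' relaxed replication variant for sensitivity analysis.
#'
#' @param state an [MtDnaState-class].
#' @param mu mutation probability per replication.
#' @param scheme `"doubling"` (default) or `"resample"`.
#' @param nextId first lineage id to mint for new mutations (default: one
#'   past the largest id present).
#' @return A list with `wildType`, `mutantCounts` (named), `copyNumber` (the
#'   per-daughter M) and `nextId`; total molecules equal `2 * copyNumber`.
#' @export
replicatePool <- function(state, mu, scheme = c("doubling", "resample"),
                          nextId = NULL) {
  stopifnot(is(state, "MtDnaState"))
  validObject(state)
  scheme <- match.arg(scheme)
  if (mu < 0 || mu >= 1) stop("mu must lie in [0, 1)")
  if (is.null(nextId)) nextId <- nextLineageId(state@mutantCounts)
  M <- state@copyNumber
  if (scheme == "doubling") {
    nNew <- stats::rbinom(1L, state@wildType, mu)
    wt <- 2L * state@wildType - nNew
    mut <- 2L * state@mutantCounts
  } else {
    # 2M draws with replacement from the M templates
    probs <- c(state@wildType, state@mutantCounts) / M
    draws <- stats::rmultinom(1L, 2L * M, probs)[, 1L]
    nNew <- stats::rbinom(1L, draws[1L], mu)
    wt <- draws[1L] - nNew
    mut <- draws[-1L]
    names(mut) <- names(state@mutantCounts)
    mut <- mut[mut > 0L]
  }
  if (nNew > 0L) {
    fresh <- stats::setNames(rep(1L, nNew),
                             as.character(nextId + seq_len(nNew) - 1))
    mut <- c(mut, fresh)
    nextId <- nextId + nNew
  }
  list(wildType = as.integer(wt), mutantCounts = as.integer2(mut),
       copyNumber = M, nextId = nextId)
}

#' Randomly segregate a doubled pool into two daughters
#'
#' Partitions the 2M-molecule pool uniformly at random into two daughters of
#' exactly M molecules each; per-lineage daughter counts follow the
#' multivariate hypergeometric law and the daughters jointly contain every
#' pool molecule.
#'
#' @param pool a pool as returned by [replicatePool()].
#' @return A list of two [MtDnaState-class] daughters.
#' @export
segregatePool <- function(pool) {
  M <- pool$copyNumber
  counts <- c(pool$wildType, pool$mutantCounts)
  if (sum(counts) != 2L * M)
    stop("pool must contain exactly 2 * copyNumber molecules")
  need <- M
  rem <- 2L * M
  take <- integer(length(counts))
  for (i in seq_along(counts)) {
    c_i <- counts[i]
    take[i] <- if (need <= 0L) 0L
      else if (need >= rem) c_i
      else stats::rhyper(1L, c_i, rem - c_i, need)
    need <- need - take[i]
    rem <- rem - c_i
  }
  mk <- function(cnt) {
    mut <- cnt[-1L]
    names(mut) <- names(pool$mutantCounts)
    mtDnaState(wildType = unname(cnt[1L]), mutantCounts = mut[mut > 0L],
               copyNumber = M)
  }
  list(mk(take), mk(counts - take))
}

#' Divide a stem cell: replicate then segregate
#'
#' Composition of [replicatePool()] and [segregatePool()]: relaxed
#' replication of the mtDNA pool followed by random segregation upon cell
#' division. Heteroplasmy is a martingale under this scheme (the expected
#' daughter mutant fraction equals the parent's).
#'
#' @inheritParams replicatePool
#' @param t age in years at which the division happens.
#' @param schedule a [MutationRateSchedule-class]; `mu` is taken as
#'   `mutationRateAt(t, schedule)` unless given directly.
#' @param mu optional explicit mutation probability (overrides the schedule).
#' @return A list of two [MtDnaState-class] daughters.
#' @examples
#' set.seed(1)
#' divideCell(mtDnaState(mutantCounts = c(L1 = 100)), mu = 0)
#' @export
divideCell <- function(state, t = 0, schedule = mutationRateSchedule(),
                       mu = NULL, scheme = c("doubling", "resample"),
                       nextId = NULL) {
  if (is.null(mu)) mu <- mutationRateAt(t, schedule)
  segregatePool(replicatePool(state, mu, scheme, nextId))
}

#' Is a stem cell OXPHOS-deficient?
#'
#' A cell is OXPHOS-deficient when its total mutant mtDNA fraction reaches the
#' deficiency threshold (boundary inclusive): 150 of 200 molecules at the
#' default 75% threshold.
#'
#' @param state an [MtDnaState-class].
#' @param theta heteroplasmy threshold in (0, 1], default 0.75.
#' @return Logical flag.
#' @export
isOxphosDeficient <- function(state, theta = 0.75) {
  stopifnot(is(state, "MtDnaState"))
  if (theta <= 0 || theta > 1) stop("theta must lie in (0, 1]")
  sum(state@mutantCounts) / state@copyNumber >= theta - 1e-12
}

# heteroplasmy of one state
heteroplasmy <- function(state) sum(state@mutantCounts) / state@copyNumber

nextLineageId <- function(mutantCounts) {
  if (length(mutantCounts) == 0L) return(1)
  ids <- suppressWarnings(as.numeric(names(mutantCounts)))
  if (any(is.na(ids))) return(length(mutantCounts) + 1)
  max(ids) + 1
}
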