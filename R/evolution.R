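#' Pareto dominance (minimization)
#'
#' `a` dominates `b` when it is no worse in every objective and strictly
#' better in at least one.  All three objectives (SAS, logP, binding
#' score) are minimized.
#'
#' @param a,b numeric objective vectors of equal length.
#' @return logical scalar.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) {
    stop_delfrag("objective vectors differ in dimension", "delfrag_shape_error")
  }
  all(a <= b) && any(a < b)
}

#' Fast non-dominated sorting
#'
#' Assigns every point its Pareto rank: rank 1 is the non-dominated set,
#' and front k is non-dominated once fronts 1..k-1 are removed
#' (the NSGA-II front-construction algorithm, using domination counts and
#' dominated-set lists).
#'
#' @param objs numeric matrix, one row per point, or a data.frame of
#'   objective columns.
#' @return integer vector of ranks (1 = best front).
#' @export
non_dominated_sort <- function(objs) {
  objs <- as.matrix(objs)
  n <- nrow(objs)
  if (n == 0) return(integer(0))
  dominated_by <- vector("list", n)  # who i dominates
  n_dom <- integer(n)                # how many dominate i
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(objs[i, ], objs[j, ])) {
        dominated_by[[i]] <- c(dominated_by[[i]], j)
      } else if (dominates(objs[j, ], objs[i, ])) {
        n_dom[i] <- n_dom[i] + 1L
      }
    }
  }
  rank <- integer(n)
  front <- which(n_dom == 0L)
  r <- 1L
  while (length(front)) {
    rank[front] <- r
    nxt <- integer(0)
    for (i in front) {
      for (j in dominated_by[[i]]) {
        n_dom[j] <- n_dom[j] - 1L
        if (n_dom[j] == 0L) nxt <- c(nxt, j)
      }
    }
    front <- nxt
    r <- r + 1L
  }
  rank
}

#' Crowding distance within a Pareto front
#'
#' The NSGA-II density estimate: for each objective the front is sorted,
#' boundary points receive infinity, and an interior point accumulates
#' the normalized gap between its two neighbours,
#' `(next - previous) / (max - min)`.  Objectives with zero range
#' contribute nothing.
#'
#' @param front numeric matrix of objective vectors (rows), all in one
#'   front.
#' @return numeric vector of crowding distances.
#' @export
crowding_distance <- function(front) {
  front <- as.matrix(front)
  n <- nrow(front)
  if (n == 0) return(numeric(0))
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (m in seq_len(ncol(front))) {
    ord <- order(front[, m])
    rng <- front[ord[n], m] - front[ord[1], m]
    d[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      for (k in 2:(n - 1)) {
        d[ord[k]] <- d[ord[k]] +
          (front[ord[k + 1], m] - front[ord[k - 1], m]) / rng
      }
    }
  }
  d
}

# rank + per-front crowding for a member data.frame with sas/logp/bas
rank_members <- function(members) {
  objs <- as.matrix(members[, c("sas", "logp", "bas")])
  finite <- is.finite(objs[, "bas"])
  rank <- rep(NA_integer_, nrow(members))
  crowd <- rep(0, nrow(members))
  if (any(finite)) {
    rank[finite] <- non_dominated_sort(objs[finite, , drop = FALSE])
    for (r in unique(rank[finite])) {
      idx <- which(!is.na(rank) & rank == r)
      crowd[idx] <- crowding_distance(objs[idx, , drop = FALSE])
    }
  }
  # molecules the scorer could not process sort behind every real front
  if (any(!finite)) {
    rank[!finite] <- max(rank, 0L, na.rm = TRUE) + 1L
    crowd[!finite] <- 0
  }
  members$rank <- rank
  members$crowding <- crowd
  members
}

#' Construct a population object
#'
#' @param members data.frame with columns `smiles`, `sas`, `logp`, `bas`
#'   (plus `rank`/`crowding` once evaluated).
#' @param latent numeric matrix of latent vectors aligned with `members`.
#' @param generation generation index (0 = initial).
#' @param size_target target population size.
#' @return object of class `del_population`.
#' @export
del_population <- function(members, latent = NULL, generation = 0L,
                           size_target = nrow(members)) {
  structure(
    list(members = members, latent = latent,
         generation = as.integer(generation),
         size_target = as.integer(size_target),
         generated = NULL),
    class = "del_population"
  )
}

#' @export
print.del_population <- function(x, ...) {
  cat(sprintf("DEL population, generation %d: %d molecules (target %d)\n",
              x$generation, nrow(x$members), x$size_target))
  if (!is.null(x$members$rank)) {
    cat(sprintf("  front 1: %d members; %d fronts\n",
                sum(x$members$rank == 1, na.rm = TRUE),
                max(x$members$rank, na.rm = TRUE)))
  }
  invisible(x)
}

#' Binary tournament selection
#'
#' Draws two distinct members and returns the index of the one that is
#' better by (rank ascending, crowding distance descending) with
#' probability `p`, otherwise the other.  Exact ties are decided by a
#' fair coin.
#'
#' @param pop a `del_population` with evaluated members.
#' @param p probability of keeping the better candidate.
#' @return integer index into `pop$members`.
#' @export
tournament_select <- function(pop, p = 0.95) {
  n <- nrow(pop$members)
  if (n < 2) {
    stop_delfrag("tournament selection needs at least two members",
                 "delfrag_population_error")
  }
  ij <- sample.int(n, 2)
  better <- tournament_better(pop$members, ij[1], ij[2])
  if (stats::runif(1) <= p) better else setdiff(ij, better)
}

tournament_better <- function(members, i, j) {
  ri <- members$rank[i]; rj <- members$rank[j]
  if (ri != rj) return(if (ri < rj) i else j)
  ci <- members$crowding[i]; cj <- members$crowding[j]
  if (ci != cj) return(if (ci > cj) i else j)
  if (stats::runif(1) < 0.5) i else j
}

#' Uniform crossover of two latent vectors
#'
#' Every coordinate is swapped between the two children with probability
#' `swap_p`, so the children's coordinate multiset equals the parents'
#' in every dimension.
#'
#' @param z1,z2 numeric vectors of equal length.
#' @param swap_p per-coordinate swap probability.
#' @return list with elements `child1`, `child2`.
#' @export
crossover_latent <- function(z1, z2, swap_p = 0.5) {
  if (length(z1) != length(z2)) {
    stop_delfrag("latent vectors differ in length", "delfrag_shape_error")
  }
  swap <- stats::runif(length(z1)) < swap_p
  c1 <- z1; c2 <- z2
  c1[swap] <- z2[swap]
  c2[swap] <- z1[swap]
  list(child1 = c1, child2 = c2)
}

#' Gaussian coordinate mutation of a latent vector
#'
#' Each coordinate is independently perturbed by `N(0, sigma^2)` noise
#' with probability `rate`; the expected number of mutated coordinates is
#' `rate * length(z)`.
#'
#' @param z numeric vector.
#' @param rate per-coordinate mutation probability in `[0, 1]`.
#' @param sigma noise standard deviation (scalar or per-coordinate).
#' @return mutated vector.
#' @export
mutate_latent <- function(z, rate = 0.01, sigma = 0.1) {
  if (rate < 0 || rate > 1) {
    stop_delfrag("mutation rate must be in [0, 1]", "delfrag_config_error")
  }
  if (any(sigma < 0)) {
    stop_delfrag("sigma must be non-negative", "delfrag_config_error")
  }
  hit <- stats::runif(length(z)) < rate
  if (any(hit)) {
    sig <- if (length(sigma) == 1) rep(sigma, length(z)) else sigma
    z[hit] <- z[hit] + stats::rnorm(sum(hit), sd = sig[hit])
  }
  z
}

#' Advance the population by one evolutionary generation
#'
#' Implements one iteration of the deep-evolutionary-learning loop:
#' tournament selection, uniform crossover and Gaussian mutation on the
#' latent vectors; decoding of the evolved latents; elimination of
#' invalid and duplicate molecules; objective evaluation of the new
#' molecules; and elitist truncation of the merged (previous + offspring)
#' pool to the target size by (rank ascending, crowding descending),
#' with at most `elite_fraction * size_target` slots taken by previous
#' members.
#'
#' @param pop evaluated `del_population` (ranks, crowding, latents set).
#' @param model a `fragment_vae` used for decoding.
#' @param config a [del_config()].
#' @param scorer binding-score function, e.g. [surrogate_bas()].
#' @return the next `del_population`; the raw decoder output (before
#'   validity and duplicate filtering) is kept in `$generated`.
#' @export
evolve_generation <- function(pop, model, config, scorer = surrogate_bas) {
  stopifnot(inherits(pop, "del_population"))
  if (is.null(pop$members$rank) || is.null(pop$latent)) {
    stop_delfrag("population must be evaluated (ranks and latents) before evolving",
                 "delfrag_population_error")
  }
  n_target <- pop$size_target
  D <- ncol(pop$latent)
  sigma <- config$mutation_sigma
  if (is.null(sigma)) {
    sigma <- 0.1 * apply(pop$latent, 2, stats::sd)
    sigma[!is.finite(sigma) | sigma == 0] <- 0.1
  }
  children <- matrix(0, 0, D)
  while (nrow(children) < n_target) {
    i <- tournament_select(pop, config$tournament_p)
    j <- tournament_select(pop, config$tournament_p)
    cx <- crossover_latent(pop$latent[i, ], pop$latent[j, ],
                           config$crossover_swap_p)
    c1 <- mutate_latent(cx$child1, config$mutation_rate, sigma)
    c2 <- mutate_latent(cx$child2, config$mutation_rate, sigma)
    children <- rbind(children, c1, c2)
  }
  children <- children[seq_len(n_target), , drop = FALSE]
  decoded <- decode(model, children)
  valid <- !is.na(decoded)
  canon <- decoded
  keep <- valid & !duplicated(canon) & !(canon %in% pop$members$smiles)
  off_latent <- children[keep, , drop = FALSE]
  off_smiles <- canon[keep]
  if (length(off_smiles)) {
    off <- evaluate_objectives(off_smiles, scorer)
    off_latent <- off_latent[match(off$smiles, off_smiles), , drop = FALSE]
  } else {
    off <- evaluate_objectives(character(0), scorer)
  }
  prev <- pop$members[, c("smiles", "sas", "logp", "bas", "mw")]
  merged <- rbind(prev, off)
  merged_latent <- rbind(pop$latent, off_latent)
  origin_prev <- c(rep(TRUE, nrow(prev)), rep(FALSE, nrow(off)))
  merged <- rank_members(merged)
  ord <- order(merged$rank, -merged$crowding)
  elite_cap <- ceiling(config$elite_fraction * n_target)
  take <- logical(nrow(merged))
  n_prev_taken <- 0L
  n_taken <- 0L
  for (k in ord) {
    if (n_taken >= n_target) break
    # the elite cap limits carry-over of dominated previous members; the
    # previous first front is always eligible, so the best front can only
    # be displaced by molecules that dominate it
    if (origin_prev[k] && merged$rank[k] > 1L && n_prev_taken >= elite_cap) next
    take[k] <- TRUE
    n_taken <- n_taken + 1L
    if (origin_prev[k]) n_prev_taken <- n_prev_taken + 1L
  }
  if (n_taken < n_target) {
    # not enough distinct offspring: the elite cap no longer displaces
    # anyone, so fill the remaining slots with the next best members
    for (k in ord) {
      if (n_taken >= n_target) break
      if (!take[k]) {
        take[k] <- TRUE
        n_taken <- n_taken + 1L
      }
    }
  }
  members <- rank_members(merged[take, , drop = FALSE])
  out <- del_population(members, merged_latent[take, , drop = FALSE],
                        generation = pop$generation + 1L,
                        size_target = n_target)
  out$generated <- decoded
  out
}

# re-encode members with the current encoder, keeping the stored latent
# where a molecule's fragments fall outside the model vocabulary
refresh_latents <- function(pop, model) {
  smiles <- pop$members$smiles
  ok <- vapply(smiles, function(s) {
    fr <- tryCatch(brics_fragment(s)$fragments, error = function(e) NULL)
    !is.null(fr) && all(fr %in% model$vocab) &&
      length(fr) < model$max_len
  }, logical(1))
  latent <- pop$latent
  if (is.null(latent)) {
    latent <- matrix(0, length(smiles), model$spec$D)
  }
  if (any(ok)) {
    latent[ok, ] <- encode(model, smiles[ok])$mean
  }
  pop$latent <- latent
  pop
}

#' Run the deep-evolutionary-learning loop
#'
#' Pretrains the fragment VAE on the (preprocessed) dataset, draws the
#' initial population from the training data, and then alternates
#' evolutionary optimization in the latent space with fine-tuning of the
#' generative model on the highest-ranked molecules, for
#' `config$generations` generations.  Smaller SAS, logP and binding
#' score are always preferred.
#'
#' @param dataset character vector of training SMILES.
#' @param config a [del_config()].
#' @param model_cfg a [model_config()].
#' @param variant generative model variant, `"jt"` or `"smiles"`.
#' @param scorer binding-score function of a SMILES vector; defaults to
#'   the deterministic surrogate.
#' @param reference_molecules optional SMILES appended to the initial
#'   population when `config$include_reference_molecules` is set (the
#'   reference workflows append known drugs here).
#' @param verbose print per-generation progress.
#' @return object of class `del_run`: list with `populations` (per
#'   generation), `metrics` (one row per generation, see
#'   [generation_report()]), `model`, `reference_point`, `config`.
#' @export
run_del <- function(dataset, config = del_config(),
                    model_cfg = model_config(), variant = c("jt", "smiles"),
                    scorer = NULL, reference_molecules = NULL,
                    verbose = FALSE) {
  variant <- match.arg(variant)
  set.seed(config$seed)
  if (is.null(scorer)) {
    seed <- config$seed
    scorer <- function(s) surrogate_bas(s, seed = seed)
  }
  data <- preprocess_dataset(dataset)
  if (length(data) < 2) {
    stop_delfrag("dataset too small after preprocessing", "delfrag_invalid_input")
  }
  if (verbose) message(sprintf("pretraining on %d molecules", length(data)))
  model <- fragment_vae(data, variant = variant, config = model_cfg,
                        epochs = config$initial_epochs, seed = config$seed)

  n0 <- min(config$population_size, length(data))
  init_smiles <- sample(data, n0)
  if (config$include_reference_molecules && length(reference_molecules)) {
    refs <- preprocess_dataset(reference_molecules)
    init_smiles <- unique(c(init_smiles, refs))
  }
  members <- rank_members(evaluate_objectives(init_smiles, scorer))
  pop <- del_population(members, generation = 0L,
                        size_target = config$population_size)
  pop$generated <- members$smiles
  initial_records <- members
  ref_point <- hv_reference_point(members)

  populations <- list(pop)
  metrics <- generation_report(pop, initial_records, ref_point,
                               training_set = data)
  if (verbose) message(sprintf("generation 0: hv %.3f", metrics$hypervolume))
  g <- 0L
  while (g < config$generations) {
    g <- g + 1L
    pop <- refresh_latents(pop, model)
    pop <- evolve_generation(pop, model, config, scorer)
    top_n <- max(2L, ceiling(config$finetune_fraction * nrow(pop$members)))
    ord <- order(pop$members$rank, -pop$members$crowding)
    elite <- pop$members[ord[seq_len(min(top_n, nrow(pop$members)))], ]
    model <- finetune(model, elite$smiles,
                      properties = elite[, c("sas", "logp", "bas")],
                      epochs = config$subsequent_epochs, generation = g,
                      annealing_rate = config$annealing_rate)
    populations[[g + 1L]] <- pop
    row <- generation_report(pop, initial_records, ref_point,
                             training_set = data)
    metrics <- rbind(metrics, row)
    if (verbose) {
      message(sprintf("generation %d: %d molecules, hv %.3f", g,
                      nrow(pop$members), row$hypervolume))
    }
  }
  structure(
    list(populations = populations, metrics = metrics, model = model,
         reference_point = ref_point, initial = initial_records,
         config = config, variant = variant, seed = config$seed,
         training_set = data),
    class = "del_run"
  )
}

#' @export
print.del_run <- function(x, ...) {
  cat(sprintf("DEL run (%s variant): %d generations, population target %d\n",
              x$variant, x$config$generations, x$config$population_size))
  cat(sprintf("  reference point: (%s)\n",
              paste(sprintf("%.2f", x$reference_point), collapse = ", ")))
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.del_run <- function(object, ...) {
  print(object)
  final <- object$populations[[length(object$populations)]]$members
  front <- final[final$rank == 1, ]
  cat(sprintf("\nFinal front 1 (%d molecules), objective means: sas %.2f, logp %.2f, bas %.2f\n",
              nrow(front), mean(front$sas), mean(front$logp), mean(front$bas)))
  invisible(object)
}

#' @export
plot.del_run <- function(x, ...) {
  m <- x$metrics
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(m$generation, m$hypervolume, type = "b", pch = 19,
                 xlab = "generation", ylab = "front-1 hypervolume", ...)
  graphics::matplot(m$generation, cbind(m$w1_sas, m$w1_logp, m$w1_bas),
                    type = "b", pch = 19, lty = 1,
                    col = c("steelblue", "darkorange", "forestgreen"),
                    xlab = "generation", ylab = "W1 distance to initial data")
  graphics::legend("topleft", legend = c("SAS", "logP", "BAS"),
                   col = c("steelblue", "darkorange", "forestgreen"),
                   lty = 1, pch = 19, bty = "n")
  invisible(x)
}
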