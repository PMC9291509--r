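#' Generative model configuration
#'
#' Defaults are the framework's reference hyperparameter settings:
#' embedding 128, hidden state 450 (junction-tree variant) or 128
#' (SMILES-fragment variant), latent dimension 64, learning rate 1e-4,
#' batch size 32 (junction-tree) or 128 (SMILES), KL weight `beta` 0.1.
#' The property-regularization weight `alpha` is not part of that table;
#' it defaults to 0.1 and is exposed here.
#'
#' @param embedding_size integer, fragment-embedding width.
#' @param hidden_size integer, width of the hidden layers.
#' @param latent_size integer, total latent dimension (split in half into
#'   tree and graph parts for the junction-tree variant).
#' @param recurrent_layers integer, number of stacked hidden layers in the
#'   encoder and decoder.
#' @param learning_rate base learning rate.
#' @param batch_size minibatch size.
#' @param beta KL-divergence weight.
#' @param alpha property squared-error weight.
#' @return object of class `model_config`.
#' @export
model_config <- function(embedding_size = 128L, hidden_size = 450L,
                         latent_size = 64L, recurrent_layers = 1L,
                         learning_rate = 1e-4, batch_size = 32L,
                         beta = 0.1, alpha = 0.1) {
  stopifnot(embedding_size > 0, hidden_size > 0, latent_size > 0,
            recurrent_layers > 0, learning_rate > 0, batch_size > 0)
  if (beta < 0 || alpha < 0) {
    stop_delfrag("beta and alpha must be non-negative", "delfrag_config_error")
  }
  structure(
    list(embedding_size = as.integer(embedding_size),
         hidden_size = as.integer(hidden_size),
         latent_size = as.integer(latent_size),
         recurrent_layers = as.integer(recurrent_layers),
         learning_rate = learning_rate,
         batch_size = as.integer(batch_size),
         beta = beta, alpha = alpha),
    class = "model_config"
  )
}

#' Deep-evolutionary-learning run configuration
#'
#' Defaults are the reference settings of the evolutionary process:
#' 10 generations, population 20000, 20 initial and 10 subsequent training
#' epochs, learning-rate annealing 0.8 per generation, tournament
#' selection probability 0.95, mutation rate 0.01.  The elite and
#' fine-tuning fractions are not stated there; they default to 0.5 and
#' 0.2 of the population respectively.
#'
#' @param generations number of evolutionary generations.
#' @param population_size target population size per generation.
#' @param initial_epochs pretraining epochs.
#' @param subsequent_epochs fine-tuning epochs per generation.
#' @param annealing_rate learning-rate multiplier per generation.
#' @param tournament_p probability that binary tournament selection
#'   returns the better of the two drawn individuals.
#' @param mutation_rate per-coordinate mutation probability.
#' @param mutation_sigma mutation step scale; `NULL` means 0.1 times the
#'   per-dimension standard deviation of the current population latents.
#' @param crossover_swap_p per-coordinate swap probability of uniform
#'   crossover.
#' @param elite_fraction maximum fraction of the next population taken
#'   from the previous population's best members.
#' @param finetune_fraction fraction of the population (best by rank and
#'   crowding) used to fine-tune the generative model each generation.
#' @param include_reference_molecules add the supplied reference molecules
#'   (e.g. known drugs) to the initial population.
#' @param seed integer seed for the whole run.
#' @return object of class `del_config`.
#' @export
del_config <- function(generations = 10L, population_size = 20000L,
                       initial_epochs = 20L, subsequent_epochs = 10L,
                       annealing_rate = 0.8, tournament_p = 0.95,
                       mutation_rate = 0.01, mutation_sigma = NULL,
                       crossover_swap_p = 0.5,
                       elite_fraction = 0.5, finetune_fraction = 0.2,
                       include_reference_molecules = FALSE, seed = 1L) {
  if (tournament_p <= 0 || tournament_p > 1) {
    stop_delfrag("tournament_p must be in (0, 1]", "delfrag_config_error")
  }
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop_delfrag("mutation_rate must be in [0, 1]", "delfrag_config_error")
  }
  stopifnot(generations >= 0, population_size > 0, annealing_rate > 0,
            elite_fraction >= 0, elite_fraction <= 1,
            finetune_fraction > 0, finetune_fraction <= 1)
  structure(
    list(generations = as.integer(generations),
         population_size = as.integer(population_size),
         initial_epochs = as.integer(initial_epochs),
         subsequent_epochs = as.integer(subsequent_epochs),
         annealing_rate = annealing_rate,
         tournament_p = tournament_p,
         mutation_rate = mutation_rate,
         mutation_sigma = mutation_sigma,
         crossover_swap_p = crossover_swap_p,
         elite_fraction = elite_fraction,
         finetune_fraction = finetune_fraction,
         include_reference_molecules = isTRUE(include_reference_molecules),
         seed = as.integer(seed)),
    class = "del_config"
  )
}

#' Docking engine configuration
#'
#' Describes one receptor/box setup for an AutoDock-Vina-compatible
#' engine.  The reference configuration targets carbonic anhydrase IX with
#' a cubic box of edge 60 Angstrom centred at (9.879, -13.774, 7.012);
#' those are the box defaults here, while the receptor file is always
#' user-supplied.
#'
#' @param receptor_path path to the receptor PDBQT file.
#' @param box_center numeric length-3, box centre in Angstrom.
#' @param box_size numeric length-3, box edge lengths in Angstrom.
#' @param engine path or name of the docking executable.
#' @param engine_seed integer seed passed to the engine.
#' @param exhaustiveness engine search exhaustiveness.
#' @return object of class `docking_config`.
#' @export
docking_config <- function(receptor_path,
                           box_center = c(9.879, -13.774, 7.012),
                           box_size = c(60, 60, 60),
                           engine = "qvina2", engine_seed = 1L,
                           exhaustiveness = 8L) {
  stopifnot(length(box_center) == 3, length(box_size) == 3)
  if (any(box_size <= 0)) {
    stop_delfrag("box_size must be positive in every dimension",
                 "delfrag_config_error")
  }
  structure(
    list(receptor_path = receptor_path, box_center = as.numeric(box_center),
         box_size = as.numeric(box_size), engine = engine,
         engine_seed = as.integer(engine_seed),
         exhaustiveness = as.integer(exhaustiveness)),
    class = "docking_config"
  )
}

#' Load a run configuration file
#'
#' Reads a YAML (or JSON) configuration with optional top-level sections
#' `del`, `model`, `docking`, `paths` and `seed`.  Unspecified fields take
#' the package defaults (the reference hyperparameter settings); unknown keys
#' are rejected so hyperparameter typos cannot pass silently.
#'
#' @param path file path.
#' @return list with elements `del` ([del_config()]), `model`
#'   ([model_config()]), `docking` (`NULL`, `"surrogate"`, or a
#'   [docking_config()]), `paths` and `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_delfrag(sprintf("config file not found: %s", path),
                 "delfrag_io_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_top <- c("del", "model", "docking", "paths", "seed")
  check_keys(raw, known_top, "top level")
  seed <- if (!is.null(raw$seed)) as.integer(raw$seed) else 1L

  del_args <- raw$del
  check_keys(del_args, setdiff(names(formals(del_config)), ""), "del")
  del <- do.call(del_config, c(del_args, list(seed = seed)[is.null(del_args$seed)]))

  model_args <- raw$model
  check_keys(model_args, names(formals(model_config)), "model")
  model <- do.call(model_config, as.list(model_args))

  docking <- NULL
  if (!is.null(raw$docking)) {
    if (identical(raw$docking, "surrogate")) {
      docking <- "surrogate"
    } else {
      check_keys(raw$docking, names(formals(docking_config)), "docking")
      docking <- do.call(docking_config, as.list(raw$docking))
    }
  }
  list(del = del, model = model, docking = docking,
       paths = raw$paths, seed = seed)
}

check_keys <- function(x, known, where) {
  if (is.null(x)) return(invisible(NULL))
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    stop_delfrag(sprintf("unknown %s config key(s): %s", where,
                         paste(extra, collapse = ", ")),
                 "delfrag_config_error")
  }
  invisible(NULL)
}
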