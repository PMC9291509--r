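#' Gaussian KL divergence against the standard normal prior
#'
#' For a diagonal Gaussian with the given mean and log-variance,
#' `KL(q || N(0, I)) = 0.5 * sum(exp(lv) + mean^2 - 1 - lv)`.
#'
#' @param mean numeric vector (or matrix, one row per sample).
#' @param log_variance numeric vector or matrix of matching shape.
#' @return a scalar for vector input; per-row values for matrix input.
#' @export
kl_gaussian <- function(mean, log_variance) {
  if (length(mean) != length(log_variance)) {
    stop_delfrag("mean and log_variance must have the same length",
                 "delfrag_shape_error")
  }
  term <- exp(log_variance) + mean^2 - 1 - log_variance
  if (is.matrix(mean)) 0.5 * rowSums(term) else 0.5 * sum(term)
}

#' Combine loss components into the property-regularized variational loss
#'
#' `total = reconstruction + beta * kl + alpha * property_se`.  With
#' `beta = 1, alpha = 0` this reduces to the plain negative ELBO.
#'
#' @param recon reconstruction loss (negative log-likelihood).
#' @param kl KL divergence to the prior.
#' @param prop_se squared error of the latent property predictor.
#' @param beta KL weight.
#' @param alpha property-loss weight.
#' @return object of class `loss_breakdown` with fields `reconstruction`,
#'   `kl`, `property_se`, `total`.
#' @export
elbo_loss <- function(recon, kl, prop_se, beta, alpha) {
  if (beta < 0 || alpha < 0) {
    stop_delfrag("beta and alpha must be non-negative", "delfrag_config_error")
  }
  stopifnot(is.finite(recon), is.finite(kl), is.finite(prop_se))
  structure(
    list(reconstruction = recon, kl = kl, property_se = prop_se,
         total = recon + beta * kl + alpha * prop_se),
    class = "loss_breakdown"
  )
}

#' Junction-tree reconstruction loss
#'
#' The tree-decoder entropy loss is the sum of its topological term
#' (existence of a child at each step) and its label term (which cluster
#' the child is); the subgraph negative log-likelihood and the optional
#' stereoisomer term are added on top.  The stereo term is 0 when
#' disabled.
#'
#' @param topology_loss,label_loss,subgraph_nll,stereo_loss non-negative
#'   components.
#' @return their sum.
#' @export
jtvae_reconstruction <- function(topology_loss, label_loss,
                                 subgraph_nll = 0, stereo_loss = 0) {
  comps <- c(topology_loss, label_loss, subgraph_nll, stereo_loss)
  if (any(comps < 0)) {
    stop_delfrag("loss components must be non-negative", "delfrag_loss_error")
  }
  (topology_loss + label_loss) + subgraph_nll + stereo_loss
}

# ---------------------------------------------------------------------------
# tokenisation

PAD_ID <- 1L
EOS_ID <- 2L
N_SPECIAL <- 2L

count_stars <- function(tokens) {
  vapply(strsplit(tokens, ""), function(ch) sum(ch == "*"), integer(1))
}

tokenize_set <- function(smiles) {
  seqs <- lapply(smiles, function(s) brics_fragment(s)$fragments)
  vocab <- sort(unique(unlist(seqs)), method = "radix")
  list(
    sequences = seqs,
    vocab = vocab,
    stars = count_stars(vocab),
    max_len = max(lengths(seqs)) + 1L  # room for the EOS token
  )
}

encode_ids <- function(seqs, vocab, max_len) {
  ids <- matrix(PAD_ID, nrow = length(seqs), ncol = max_len)
  for (i in seq_along(seqs)) {
    hit <- match(seqs[[i]], vocab)
    if (anyNA(hit)) {
      stop_delfrag(
        sprintf("fragment cluster not in the model vocabulary: '%s'",
                seqs[[i]][which(is.na(hit))[1]]),
        "delfrag_oov_error"
      )
    }
    row <- c(hit + N_SPECIAL, EOS_ID)
    if (length(row) > max_len) {
      stop_delfrag("fragment sequence longer than the model's maximum length",
                   "delfrag_oov_error")
    }
    ids[i, seq_along(row)] <- row
  }
  ids
}

# ---------------------------------------------------------------------------
# parameters and numerics

init_params <- function(V, E, H, D, L, n_layers, Hp = 32L, K = 3L, seed = 1L) {
  set.seed(seed)
  rnorm_mat <- function(nr, nc) {
    matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
  }
  p <- list(emb = rnorm_mat(V, E))
  in_dim <- L * E
  for (l in seq_len(n_layers)) {
    p[[paste0("enc_W", l)]] <- rnorm_mat(in_dim, H)
    p[[paste0("enc_b", l)]] <- numeric(H)
    in_dim <- H
  }
  p$W_mu <- rnorm_mat(H, D); p$b_mu <- numeric(D)
  p$W_lv <- rnorm_mat(H, D); p$b_lv <- numeric(D)
  in_dim <- D
  for (l in seq_len(n_layers)) {
    p[[paste0("dec_W", l)]] <- rnorm_mat(in_dim, H)
    p[[paste0("dec_b", l)]] <- numeric(H)
    in_dim <- H
  }
  p$W_out <- rnorm_mat(H, L * V); p$b_out <- numeric(L * V)
  p$prop_W1 <- rnorm_mat(D, Hp); p$prop_b1 <- numeric(Hp)
  p$prop_W2 <- rnorm_mat(Hp, K); p$prop_b2 <- numeric(K)
  p
}

affine <- function(x, W, b) sweep(x %*% W, 2, b, "+")

mlp_forward <- function(x, params, prefix, n_layers) {
  acts <- vector("list", n_layers + 1)
  acts[[1]] <- x
  for (l in seq_len(n_layers)) {
    acts[[l + 1]] <- tanh(affine(acts[[l]],
                                 params[[paste0(prefix, "_W", l)]],
                                 params[[paste0(prefix, "_b", l)]]))
  }
  acts
}

mlp_backward <- function(dtop, acts, params, prefix, n_layers, grads) {
  d <- dtop
  for (l in rev(seq_len(n_layers))) {
    d <- d * (1 - acts[[l + 1]]^2)
    grads[[paste0(prefix, "_W", l)]] <- crossprod(acts[[l]], d)
    grads[[paste0(prefix, "_b", l)]] <- colSums(d)
    d <- d %*% t(params[[paste0(prefix, "_W", l)]])
  }
  list(grads = grads, dx = d)
}

# Forward pass with loss; returns cache for the backward pass.
vae_forward <- function(params, ids, y, eps, spec) {
  B <- nrow(ids); L <- spec$L; V <- spec$V
  emb <- params$emb
  Xe <- matrix(0, B, L * spec$E)
  for (t in seq_len(L)) {
    Xe[, ((t - 1) * spec$E + 1):(t * spec$E)] <- emb[ids[, t], , drop = FALSE]
  }
  enc_acts <- mlp_forward(Xe, params, "enc", spec$n_layers)
  h_e <- enc_acts[[spec$n_layers + 1]]
  mu <- affine(h_e, params$W_mu, params$b_mu)
  lv <- pmin(pmax(affine(h_e, params$W_lv, params$b_lv), -10), 10)
  z <- mu + exp(lv / 2) * eps
  dec_acts <- mlp_forward(z, params, "dec", spec$n_layers)
  h_d <- dec_acts[[spec$n_layers + 1]]
  logits <- affine(h_d, params$W_out, params$b_out)

  mask <- t(apply(ids, 1, function(r) {
    e <- match(EOS_ID, r)
    as.numeric(seq_len(L) <= e)
  }))
  if (L == 1) mask <- matrix(mask, ncol = 1)
  probs <- vector("list", L)
  ce_tok <- matrix(0, B, L)
  for (t in seq_len(L)) {
    lg <- logits[, ((t - 1) * V + 1):(t * V), drop = FALSE]
    lg <- lg - apply(lg, 1, max)
    p <- exp(lg); p <- p / rowSums(p)
    probs[[t]] <- p
    ce_tok[, t] <- -log(pmax(p[cbind(seq_len(B), ids[, t])], 1e-12)) * mask[, t]
  }
  is_eos <- ids == EOS_ID
  topo <- sum(ce_tok[is_eos]) / B      # stop/continue decision
  labl <- sum(ce_tok[!is_eos]) / B     # which fragment label
  recon <- topo + labl
  klv <- kl_gaussian(mu, lv)
  kl <- mean(klv)
  hp <- tanh(affine(z, params$prop_W1, params$prop_b1))
  yhat <- affine(hp, params$prop_W2, params$prop_b2)
  se <- mean(rowSums((yhat - y)^2))
  total <- recon + spec$beta * kl + spec$alpha * se
  list(Xe = Xe, enc_acts = enc_acts, mu = mu, lv = lv, z = z,
       dec_acts = dec_acts, probs = probs, mask = mask, hp = hp, yhat = yhat,
       topo = topo, label = labl, recon = recon, kl = kl, se = se,
       total = total)
}

vae_backward <- function(params, ids, y, eps, spec, cache) {
  B <- nrow(ids); L <- spec$L; V <- spec$V
  grads <- list()
  # decoder head
  dlogits <- matrix(0, B, L * V)
  for (t in seq_len(L)) {
    G <- cache$probs[[t]]
    G[cbind(seq_len(B), ids[, t])] <- G[cbind(seq_len(B), ids[, t])] - 1
    dlogits[, ((t - 1) * V + 1):(t * V)] <- G * cache$mask[, t] / B
  }
  h_d <- cache$dec_acts[[spec$n_layers + 1]]
  grads$W_out <- crossprod(h_d, dlogits)
  grads$b_out <- colSums(dlogits)
  dh_d <- dlogits %*% t(params$W_out)
  bk <- mlp_backward(dh_d, cache$dec_acts, params, "dec", spec$n_layers, grads)
  grads <- bk$grads
  dz <- bk$dx
  # property head
  dyhat <- 2 * (cache$yhat - y) * spec$alpha / B
  grads$prop_W2 <- crossprod(cache$hp, dyhat)
  grads$prop_b2 <- colSums(dyhat)
  dhp <- (dyhat %*% t(params$prop_W2)) * (1 - cache$hp^2)
  grads$prop_W1 <- crossprod(cache$z, dhp)
  grads$prop_b1 <- colSums(dhp)
  dz <- dz + dhp %*% t(params$prop_W1)
  # reparameterization + KL
  dmu <- dz + spec$beta * cache$mu / B
  dlv <- dz * 0.5 * exp(cache$lv / 2) * eps +
    spec$beta * 0.5 * (exp(cache$lv) - 1) / B
  h_e <- cache$enc_acts[[spec$n_layers + 1]]
  grads$W_mu <- crossprod(h_e, dmu); grads$b_mu <- colSums(dmu)
  grads$W_lv <- crossprod(h_e, dlv); grads$b_lv <- colSums(dlv)
  dh_e <- dmu %*% t(params$W_mu) + dlv %*% t(params$W_lv)
  bk <- mlp_backward(dh_e, cache$enc_acts, params, "enc", spec$n_layers, grads)
  grads <- bk$grads
  dXe <- bk$dx
  # embedding
  grads$emb <- matrix(0, nrow(params$emb), ncol(params$emb))
  for (t in seq_len(L)) {
    dslice <- dXe[, ((t - 1) * spec$E + 1):(t * spec$E), drop = FALSE]
    for (i in seq_len(B)) {
      grads$emb[ids[i, t], ] <- grads$emb[ids[i, t], ] + dslice[i, ]
    }
  }
  grads
}

adam_step <- function(params, grads, state, lr,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---------------------------------------------------------------------------
# fitting

#' Fit a property-regularized fragment variational autoencoder
#'
#' Molecules are represented as BRICS fragment sequences (see
#' [brics_fragment()]) and modelled by a variational autoencoder whose
#' latent space is regularized by a multilayer-perceptron property
#' predictor: the training loss is
#' `reconstruction + beta * KL + alpha * SE(f(z), y)` where `y` holds the
#' three standardized objectives (SAS, logP, binding score).  Two
#' variants are available.  The `"jt"` (junction-tree style) variant
#' splits the latent vector into tree and graph halves and decodes with
#' per-step validity checking, assembling fragments cluster by cluster so
#' that every decoded molecule is chemically valid by construction.  The
#' `"smiles"` variant decodes the fragment sequence greedily without
#' guards and may emit invalid sequences, which are flagged rather than
#' raised.
#'
#' @param x character vector of training SMILES (at least 2 molecules).
#' @param properties optional numeric matrix/data.frame with columns
#'   `sas`, `logp`, `bas`; computed with [evaluate_objectives()] and the
#'   surrogate binding scorer when omitted.
#' @param variant `"jt"` or `"smiles"`.
#' @param config a [model_config()].
#' @param epochs number of training epochs.
#' @param seed integer seed controlling initialisation, minibatch order
#'   and reparameterization noise.
#' @param verbose print per-epoch losses.
#' @return an object of class `fragment_vae` with, among others, elements
#'   `params` (weights), `vocab`, `history` (per-epoch loss data.frame),
#'   and `config`.
#' @seealso [encode()], [decode()], [sample_prior()], [finetune()]
#' @export
fragment_vae <- function(x, properties = NULL, variant = c("jt", "smiles"),
                         config = model_config(), epochs = 20L, seed = 1L,
                         verbose = FALSE) {
  variant <- match.arg(variant)
  x <- unique(canonical_smiles(x))
  x <- x[!is.na(x)]
  if (length(x) < 2) {
    stop_delfrag("need at least two valid training molecules",
                 "delfrag_invalid_input")
  }
  if (is.null(properties)) {
    obj <- evaluate_objectives(x, function(s) surrogate_bas(s, seed = seed))
    properties <- as.matrix(obj[, c("sas", "logp", "bas")])
  } else {
    properties <- as.matrix(as.data.frame(properties)[, c("sas", "logp", "bas")])
  }
  stopifnot(nrow(properties) == length(x))
  center <- colMeans(properties)
  scale <- apply(properties, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  y <- sweep(sweep(properties, 2, center), 2, scale, "/")

  tk <- tokenize_set(x)
  V <- length(tk$vocab) + N_SPECIAL
  L <- tk$max_len
  spec <- list(V = V, E = config$embedding_size, H = config$hidden_size,
               D = config$latent_size, L = L,
               n_layers = config$recurrent_layers,
               beta = config$beta, alpha = config$alpha)
  params <- init_params(V, spec$E, spec$H, spec$D, L, spec$n_layers,
                        seed = seed)
  model <- structure(
    list(params = params, spec = spec, config = config, variant = variant,
         vocab = tk$vocab, vocab_stars = tk$stars, max_len = L,
         prop_center = center, prop_scale = scale,
         train_smiles = x, train_sequences = tk$sequences,
         generation = 0L, seed = seed,
         adam = list(t = 0,
                     m = lapply(params, function(p) p * 0),
                     v = lapply(params, function(p) p * 0)),
         history = NULL),
    class = "fragment_vae"
  )
  train_epochs(model, x, y, epochs = epochs,
               lr = config$learning_rate, seed = seed, verbose = verbose)
}

#' @rdname fragment_vae
#' @export
pretrain <- function(x, properties = NULL, variant = c("jt", "smiles"),
                     config = model_config(), epochs = 20L, seed = 1L,
                     verbose = FALSE) {
  fragment_vae(x, properties, variant, config, epochs, seed, verbose)
}

train_epochs <- function(model, x, y, epochs, lr, seed, verbose = FALSE) {
  ids <- encode_ids(lapply(x, function(s) brics_fragment(s)$fragments),
                    model$vocab, model$max_len)
  B <- model$config$batch_size
  n <- nrow(ids)
  set.seed(seed + 7 * model$generation)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot <- c(recon = 0, topo = 0, label = 0, kl = 0, se = 0, total = 0)
    nb <- 0
    for (start in seq(1, n, by = B)) {
      idx <- ord[start:min(start + B - 1, n)]
      bi <- ids[idx, , drop = FALSE]
      by <- y[idx, , drop = FALSE]
      eps <- matrix(stats::rnorm(length(idx) * model$spec$D),
                    length(idx), model$spec$D)
      cache <- vae_forward(model$params, bi, by, eps, model$spec)
      grads <- vae_backward(model$params, bi, by, eps, model$spec, cache)
      upd <- adam_step(model$params, grads, model$adam, lr)
      model$params <- upd$params
      model$adam <- upd$state
      tot <- tot + c(cache$recon, cache$topo, cache$label, cache$kl,
                     cache$se, cache$total)
      nb <- nb + 1
    }
    avg <- tot / nb
    if (!is.finite(avg[["total"]])) {
      stop_delfrag(sprintf("training diverged at epoch %d (non-finite loss)", ep),
                   "delfrag_training_error")
    }
    model$history <- rbind(model$history, data.frame(
      generation = model$generation, epoch = ep,
      reconstruction = avg[["recon"]], topology = avg[["topo"]],
      label = avg[["label"]], kl = avg[["kl"]],
      property_se = avg[["se"]], total = avg[["total"]], lr = lr
    ))
    if (verbose) {
      message(sprintf("epoch %3d  recon %.4f  kl %.4f  se %.4f  total %.4f",
                      ep, avg[["recon"]], avg[["kl"]], avg[["se"]],
                      avg[["total"]]))
    }
  }
  model
}

#' Fine-tune a fitted model on elite molecules
#'
#' Continues training on a new (typically elite) molecule set with the
#' learning rate annealed as `base_lr * annealing_rate^generation`.
#' Molecules containing fragments outside the model vocabulary are
#' dropped with a message (the vocabulary is fixed at pretraining).
#'
#' @param model a [fragment_vae()] object.
#' @param x character vector of SMILES.
#' @param properties optional objective matrix as in [fragment_vae()];
#'   recomputed with the surrogate scorer when omitted.
#' @param epochs fine-tuning epochs.
#' @param generation generation index used for annealing (defaults to one
#'   past the model's stored generation).
#' @param annealing_rate learning-rate decay per generation.
#' @return the updated `fragment_vae` object.
#' @export
finetune <- function(model, x, properties = NULL, epochs = 10L,
                     generation = NULL, annealing_rate = 0.8) {
  stopifnot(inherits(model, "fragment_vae"))
  x <- unique(canonical_smiles(x))
  x <- x[!is.na(x)]
  known <- vapply(x, function(s) {
    all(brics_fragment(s)$fragments %in% model$vocab) &&
      length(brics_fragment(s)$fragments) < model$max_len
  }, logical(1))
  if (any(!known)) {
    message(sprintf("finetune: dropped %d molecules with out-of-vocabulary fragments",
                    sum(!known)))
    x <- x[known]
    if (!is.null(properties)) {
      properties <- as.data.frame(properties)[known, , drop = FALSE]
    }
  }
  if (length(x) < 2) {
    message("finetune: fewer than two usable molecules, model unchanged")
    return(model)
  }
  if (is.null(properties)) {
    obj <- evaluate_objectives(x, function(s) surrogate_bas(s, seed = model$seed))
    properties <- obj[, c("sas", "logp", "bas")]
  }
  properties <- as.matrix(as.data.frame(properties)[, c("sas", "logp", "bas")])
  y <- sweep(sweep(properties, 2, model$prop_center), 2, model$prop_scale, "/")
  if (is.null(generation)) generation <- model$generation + 1L
  model$generation <- as.integer(generation)
  lr <- model$config$learning_rate * annealing_rate^generation
  train_epochs(model, x, y, epochs = epochs, lr = lr,
               seed = model$seed, verbose = FALSE)
}

# ---------------------------------------------------------------------------
# encode / decode / sample

#' Encode molecules into the latent space
#'
#' Maps molecules to the parameters of their posterior Gaussian and one
#' reparameterized sample.  The mean is deterministic given the model;
#' the sample is `mean + exp(log_variance / 2) * epsilon` with the drawn
#' `epsilon` recorded.  For the junction-tree variant the first half of
#' the latent vector is the tree part `z_T`, the second the graph part
#' `z_G`.
#'
#' @param model a `fragment_vae` object.
#' @param smiles character vector of molecules; every fragment must be in
#'   the model vocabulary (otherwise an out-of-vocabulary error naming
#'   the fragment is raised).
#' @return list with matrices `mean`, `log_variance`, `sample`, `epsilon`
#'   (rows are molecules).
#' @export
encode <- function(model, smiles) {
  stopifnot(inherits(model, "fragment_vae"))
  seqs <- lapply(smiles, function(s) brics_fragment(s)$fragments)
  ids <- encode_ids(seqs, model$vocab, model$max_len)
  spec <- model$spec
  Xe <- matrix(0, nrow(ids), spec$L * spec$E)
  for (t in seq_len(spec$L)) {
    Xe[, ((t - 1) * spec$E + 1):(t * spec$E)] <-
      model$params$emb[ids[, t], , drop = FALSE]
  }
  h_e <- mlp_forward(Xe, model$params, "enc", spec$n_layers)[[spec$n_layers + 1]]
  mu <- affine(h_e, model$params$W_mu, model$params$b_mu)
  lv <- pmin(pmax(affine(h_e, model$params$W_lv, model$params$b_lv), -10), 10)
  eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  list(mean = mu, log_variance = lv, sample = mu + exp(lv / 2) * eps,
       epsilon = eps)
}

decoder_logits <- function(model, z) {
  spec <- model$spec
  h_d <- mlp_forward(z, model$params, "dec", spec$n_layers)[[spec$n_layers + 1]]
  affine(h_d, model$params$W_out, model$params$b_out)
}

#' Decode latent vectors into molecules
#'
#' Greedy decoding of the fragment sequence.  For the junction-tree
#' variant decoding is guarded: at every step only fragments whose
#' attachment arity can extend the current partial assembly are eligible,
#' the partial molecule is assembled and sanitized, and a failing
#' candidate is replaced by the next best one -- so decoded molecules are
#' chemically valid by construction.  The SMILES variant decodes
#' unguarded and invalid outputs are returned as `NA` (flagged, not an
#' error).  Decoding the same latent matrix twice gives the same
#' molecules.
#'
#' @param model a `fragment_vae` object.
#' @param z numeric matrix of latent vectors (rows) or a single vector.
#' @param guarded override the variant's default guarding.
#' @return character vector of SMILES (`NA` for invalid unguarded
#'   decodes).
#' @export
decode <- function(model, z, guarded = NULL) {
  stopifnot(inherits(model, "fragment_vae"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) != model$spec$D) {
    stop_delfrag("latent dimension does not match the model",
                 "delfrag_shape_error")
  }
  if (is.null(guarded)) guarded <- model$variant == "jt"
  if (nrow(z) == 0) return(character(0))
  logits <- decoder_logits(model, z)
  if (guarded) decode_guarded(model, logits) else decode_plain(model, logits)
}

# token ids (3..V) sorted by decreasing logit, restricted to `allowed`
ranked_tokens <- function(lg, allowed) {
  cand <- which(allowed)
  cand[order(lg[cand], decreasing = TRUE)]
}

decode_plain <- function(model, logits) {
  B <- nrow(logits); V <- model$spec$V; L <- model$spec$L
  seqs <- vector("list", B)
  for (i in seq_len(B)) {
    toks <- character(0)
    for (t in seq_len(L)) {
      lg <- logits[i, ((t - 1) * V + 1):(t * V)]
      lg[PAD_ID] <- -Inf
      if (t == 1) lg[EOS_ID] <- -Inf
      pick <- which.max(lg)
      if (pick == EOS_ID) break
      toks <- c(toks, model$vocab[pick - N_SPECIAL])
    }
    seqs[[i]] <- toks
  }
  out <- rep(NA_character_, B)
  has <- lengths(seqs) > 0
  if (any(has)) out[has] <- assemble_chain(seqs[has], allow_open = FALSE)
  out
}

decode_guarded <- function(model, logits, max_tries = 8L) {
  B <- nrow(logits); V <- model$spec$V; L <- model$spec$L
  stars <- model$vocab_stars
  seqs <- vector("list", B)
  open <- integer(B)          # free attachment points on the chain
  done <- logical(B)
  prefix_smiles <- rep(NA_character_, B)
  for (t in seq_len(L)) {
    active <- which(!done)
    if (!length(active)) break
    # candidate ranking per sequence under arity constraints
    cand_rank <- vector("list", B)
    for (i in active) {
      lg <- logits[i, ((t - 1) * V + 1):(t * V)]
      allowed <- rep(FALSE, V)
      if (t == 1) {
        # the chain must be closable in the remaining L - 1 slots
        ok <- stars <= L - 1L
      } else if (open[i] == 0) {
        done[i] <- TRUE
        next
      } else {
        # attaching consumes one open star and adds (stars - 1) new ones
        ok <- stars >= 1L & (open[i] + stars - 2L) <= (L - t)
      }
      allowed[which(ok) + N_SPECIAL] <- TRUE
      cand_rank[[i]] <- ranked_tokens(lg, allowed)
    }
    pending <- setdiff(which(!done), which(vapply(cand_rank, is.null, logical(1))))
    tries <- 0L
    choice <- integer(B)
    while (length(pending) && tries < max_tries) {
      tries <- tries + 1L
      for (i in pending) {
        if (length(cand_rank[[i]])) {
          choice[i] <- cand_rank[[i]][1]
          cand_rank[[i]] <- cand_rank[[i]][-1]
        } else {
          choice[i] <- 0L
        }
      }
      feasible <- pending[choice[pending] > 0L]
      infeasible <- pending[choice[pending] == 0L]
      # no arity-compatible candidate survived the chemistry checks:
      # truncate to the longest closed prefix (practically unreachable)
      for (i in infeasible) {
        done[i] <- TRUE
        seqs[[i]] <- truncate_closed(seqs[[i]], model)
        open[i] <- 0L
      }
      if (!length(feasible)) break
      trial_seqs <- lapply(feasible, function(i) {
        c(seqs[[i]], model$vocab[choice[i] - N_SPECIAL])
      })
      res <- assemble_chain(trial_seqs, allow_open = TRUE)
      ok <- !is.na(res)
      for (k in seq_along(feasible)) {
        i <- feasible[k]
        if (ok[k]) {
          tok <- model$vocab[choice[i] - N_SPECIAL]
          seqs[[i]] <- c(seqs[[i]], tok)
          open[i] <- if (t == 1) stars[choice[i] - N_SPECIAL] else
            open[i] + stars[choice[i] - N_SPECIAL] - 2L
          prefix_smiles[i] <- res[k]
        }
      }
      pending <- feasible[!ok]
    }
    for (i in pending) {  # tries exhausted
      done[i] <- TRUE
      seqs[[i]] <- truncate_closed(seqs[[i]], model)
      open[i] <- 0L
    }
  }
  finals <- assemble_chain(seqs[lengths(seqs) > 0], allow_open = FALSE)
  out <- rep(NA_character_, B)
  out[lengths(seqs) > 0] <- finals
  out
}

# longest prefix of a fragment chain with no open attachment points
truncate_closed <- function(toks, model) {
  if (!length(toks)) return(toks)
  s <- count_stars(toks)
  open <- cumsum(c(s[1], if (length(s) > 1) s[-1] - 2L))
  closed <- which(open == 0L)
  if (!length(closed)) return(character(0))
  toks[seq_len(max(closed))]
}

#' Sample molecules from the prior
#'
#' Draws `n` latent vectors from the standard normal prior and decodes
#' them.  Reproducible under `seed`.
#'
#' @param model a `fragment_vae` object.
#' @param n number of samples.
#' @param seed integer seed.
#' @return character vector of length `n` (`NA` entries possible only for
#'   the unguarded SMILES variant).
#' @export
sample_prior <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "fragment_vae"), n >= 0)
  if (n == 0) return(character(0))
  set.seed(seed)
  z <- matrix(stats::rnorm(n * model$spec$D), n, model$spec$D)
  decode(model, z)
}

# ---------------------------------------------------------------------------
# methods

#' @export
print.fragment_vae <- function(x, ...) {
  cat(sprintf("Property-regularized fragment VAE (%s variant)\n",
              if (x$variant == "jt") "junction-tree" else "SMILES-fragment"))
  cat(sprintf("  vocabulary: %d fragments; max sequence length %d\n",
              length(x$vocab), x$max_len))
  cat(sprintf("  latent %d, hidden %d x %d, embedding %d\n",
              x$spec$D, x$spec$H, x$spec$n_layers, x$spec$E))
  cat(sprintf("  trained on %d molecules, %d epochs (generation %d)\n",
              length(x$train_smiles), nrow(x$history), x$generation))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final loss: recon %.3f + %.2g*kl %.3f + %.2g*se %.3f = %.3f\n",
                last$reconstruction, x$spec$beta, last$kl, x$spec$alpha,
                last$property_se, last$total))
  }
  invisible(x)
}

#' @export
summary.fragment_vae <- function(object, ...) {
  print(object)
  cat("\nLoss history (last 5 epochs):\n")
  print(utils::tail(object$history[, c("generation", "epoch", "reconstruction",
                                       "kl", "property_se", "total", "lr")], 5),
        row.names = FALSE)
  invisible(object)
}

#' @export
coef.fragment_vae <- function(object, ...) object$params

#' Predict from a fitted fragment VAE
#'
#' @param object a `fragment_vae`.
#' @param newdata character vector of SMILES.
#' @param type `"latent"` for posterior means, `"properties"` for the
#'   latent property predictor's estimates (back-transformed to the
#'   original objective scales).
#' @param ... unused.
#' @export
predict.fragment_vae <- function(object, newdata,
                                 type = c("latent", "properties"), ...) {
  type <- match.arg(type)
  enc <- encode(object, newdata)
  if (type == "latent") return(enc$mean)
  hp <- tanh(affine(enc$mean, object$params$prop_W1, object$params$prop_b1))
  yhat <- affine(hp, object$params$prop_W2, object$params$prop_b2)
  out <- sweep(sweep(yhat, 2, object$prop_scale, "*"), 2, object$prop_center, "+")
  colnames(out) <- c("sas", "logp", "bas")
  out
}

#' @export
simulate.fragment_vae <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) seed <- 1L
  sample_prior(object, nsim, seed = seed)
}

#' @export
plot.fragment_vae <- function(x, ...) {
  h <- x$history
  graphics::matplot(seq_len(nrow(h)),
                    cbind(h$total, h$reconstruction, h$kl, h$property_se),
                    type = "l", lty = 1, lwd = 2,
                    col = c("black", "steelblue", "darkorange", "forestgreen"),
                    xlab = "epoch (cumulative)", ylab = "loss", ...)
  graphics::legend("topright", legend = c("total", "reconstruction", "KL",
                                          "property SE"),
                   col = c("black", "steelblue", "darkorange", "forestgreen"),
                   lty = 1, lwd = 2, bty = "n")
  invisible(x)
}

#' @export
residuals.fragment_vae <- function(object, ...) {
  obs <- evaluate_objectives(object$train_smiles,
                             function(s) surrogate_bas(s, seed = object$seed))
  pred <- predict(object, object$train_smiles, type = "properties")
  as.matrix(obs[, c("sas", "logp", "bas")]) - pred
}
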