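# The equivariant vector-scalar message-passing network.
#
# Architecture: embedding block -> L stacked blocks (Scalar2Vec: edge-fusion
# attention + vector messages; Vec2Scalar: runtime-angle and runtime-dihedral
# scalar updates) -> gated equivariant output blocks -> property head.
# Scalars h (per node) and f (per directed edge) are rotation invariant; the
# vector embedding v (per node, 3 x F spatial channels at l_max = 1, 8 x F
# with the order-2 spherical extension) is equivariant.  The energy head's
# forces are the exact negative coordinate gradient of the predicted energy,
# obtained by reverse-mode differentiation on the tape — the model is an
# energy-conserving potential by construction.
#
# All forward passes are built from R/autodiff.R primitives, so
# d(forces)/d(parameters) — needed by the combined energy/force loss — is a
# second backward pass over the same tape.

#' Model configuration
#'
#' @param n_blocks number of message-passing blocks L (default 9).
#' @param hidden_dim embedding dimension F (default 256); must be divisible
#'   by `n_heads`.
#' @param l_max spherical order of the vector channels: 1 (geometric, 3
#'   spatial components) or 2 (adds the 5 order-2 real harmonics).
#' @param cutoff neighbor cutoff radius, Angstrom (default 5).
#' @param n_rbf number of radial basis functions (default 32).
#' @param n_heads attention heads (default 8).
#' @param activation nonlinearity tag; only "silu" is implemented.
#' @param use_improper add the vertex-centred improper-angle term to the edge
#'   update (default off).
#' @param head one of "energy_forces", "dipole", "spatial_extent", "scalar".
#' @param max_z largest embeddable atomic number.
#' @return object of class `model_config`.
#' @export
model_config <- function(n_blocks = 9L, hidden_dim = 256L, l_max = 1L,
                         cutoff = 5, n_rbf = 32L, n_heads = 8L,
                         activation = "silu", use_improper = FALSE,
                         head = c("energy_forces", "dipole",
                                  "spatial_extent", "scalar"),
                         max_z = 36L) {
  head <- match.arg(head)
  stopifnot(n_blocks >= 1L, hidden_dim %% n_heads == 0L,
            l_max %in% c(1L, 2L), cutoff > 0, n_rbf >= 2L,
            identical(activation, "silu"))
  structure(list(n_blocks = as.integer(n_blocks),
                 hidden_dim = as.integer(hidden_dim),
                 l_max = as.integer(l_max), cutoff = cutoff,
                 n_rbf = as.integer(n_rbf), n_heads = as.integer(n_heads),
                 activation = activation, use_improper = use_improper,
                 head = head, max_z = as.integer(max_z)),
            class = "model_config")
}

n_spatial <- function(cfg) if (cfg$l_max == 1L) 3L else 8L

## ---- parameters ----------------------------------------------------------

unif_init <- function(nr, nc, fan_in = nr) {
  a <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

#' Initialize a model
#'
#' Uniform fan-based initialization for weight matrices, zero biases; vector
#' pathways carry no biases (required for equivariance).
#'
#' @param config a [model_config()].
#' @param seed RNG seed fixing the parameter draw.
#' @return object of class `rgc_model`: list with `config` and the flat
#'   named parameter list `params`.
#' @export
rgc_model <- function(config = model_config(), seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  Fd <- config$hidden_dim; K <- config$n_rbf
  p <- list()
  p$emb_table <- unif_init(config$max_z, Fd, fan_in = Fd)
  p$emb_Wnbr <- unif_init(K, Fd)
  p$emb_Wemb <- unif_init(2L * Fd, Fd)
  p$emb_bemb <- matrix(0, 1L, Fd)
  p$emb_Wf <- unif_init(K, Fd)
  p$emb_bf <- matrix(0, 1L, Fd)
  for (l in seq_len(config$n_blocks)) {
    pre <- sprintf("bl%d_", l)
    lin <- function(nm, nr = Fd, nc = Fd, bias = TRUE) {
      p[[paste0(pre, "W", nm)]] <<- unif_init(nr, nc)
      if (bias) p[[paste0(pre, "b", nm)]] <<- matrix(0, 1L, nc)
    }
    lin("q"); lin("k"); lin("v")
    lin("dk"); lin("dv")                      # edge fusions of f
    lin("du"); lin("dvv")                     # vector-message denses
    lin("vm")                                 # gate on aggregated message
    lin("vgate", bias = FALSE)                # v linear (no bias)
    lin("t", bias = FALSE); lin("s", bias = FALSE)
    lin("angle"); lin("res")
    lin("rt", bias = FALSE); lin("rs", bias = FALSE)
    lin("dd")                                 # Dense_Dihedral
    if (config$use_improper) {
      lin("it", bias = FALSE); lin("is", bias = FALSE)
      lin("di")
    }
  }
  ## two gated equivariant output blocks: F -> F/2 -> 1
  dims <- c(Fd, max(Fd %/% 2L, 1L), 1L)
  for (ob in 1:2) {
    fin <- dims[ob]; fout <- dims[ob + 1L]
    pre <- sprintf("out%d_", ob)
    p[[paste0(pre, "Wo1")]] <- unif_init(fin, fout)
    p[[paste0(pre, "Wo2")]] <- unif_init(fout + fin, fout)
    p[[paste0(pre, "bo2")]] <- matrix(0, 1L, fout)
    p[[paste0(pre, "Wo3")]] <- unif_init(fout, fout)
    p[[paste0(pre, "bo3")]] <- matrix(0, 1L, fout)
    p[[paste0(pre, "Wo4")]] <- unif_init(fin, fout)
    p[[paste0(pre, "Wo5")]] <- unif_init(fout, fout)
    p[[paste0(pre, "bo5")]] <- matrix(0, 1L, fout)
  }
  structure(list(config = config, params = p,
                 output_scale = 1, output_shift = 0),
            class = "rgc_model")
}

# per-frame affine output calibration: E = scale * sum(h) + shift
model_scale <- function(model) model$output_scale %||% 1
model_shift <- function(model) model$output_shift %||% 0

#' @export
print.rgc_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat(sprintf(
    "<rgc_model: %d blocks, %d channels, l_max %d, %d parameters, head %s>\n",
    x$config$n_blocks, x$config$hidden_dim, x$config$l_max, np,
    x$config$head))
  invisible(x)
}

## ---- graph-building helpers ---------------------------------------------

ad_linear <- function(x, W, b = NULL) {
  if (is.null(b)) ad_matmul(x, W) else ad_affine(x, W, b)
}

ad_dense <- function(x, W, b) ad_silu(ad_linear(x, W, b))

#' Cosine cutoff values (numeric helper)
#'
#' `phi(r) = 0.5 (cos(pi r / r_c) + 1)` for r <= r_c, zero beyond; smooth
#' radial weight with phi(0) = 1 and phi(r_c) = 0.
#'
#' @param r distances, Angstrom.
#' @param cutoff cutoff radius r_c.
#' @return numeric vector of weights in [0, 1].
#' @export
cosine_cutoff <- function(r, cutoff) {
  ifelse(r <= cutoff, 0.5 * (cos(pi * r / cutoff) + 1), 0)
}

rbf_centers <- function(cfg) seq(exp(-cfg$cutoff), 1, length.out = cfg$n_rbf)
rbf_beta <- function(cfg) (2 / cfg$n_rbf * (1 - exp(-cfg$cutoff)))^-2

# exponential-Gaussian radial basis on exp(-r) abscissae (values in [0, 1])
ad_rbf <- function(r, cfg) {
  E <- nrow(r$value)
  mu <- if (E > 0L) matrix(rbf_centers(cfg), E, cfg$n_rbf, byrow = TRUE)
        else matrix(0, 0L, cfg$n_rbf)
  er <- ad_bcast_cols(ad_exp(ad_neg(r)), cfg$n_rbf)
  diff <- ad_addc(er, -mu)
  ad_exp(ad_scale(ad_mul(diff, diff), -rbf_beta(cfg)))
}

ad_cosine_cutoff <- function(r, cutoff) {
  ad_addc(ad_scale(ad_cos(ad_scale(r, pi / cutoff)), 0.5), 0.5)
}

# order-2 real spherical harmonic columns of unit vectors (E x 5)
ad_sh2_cols <- function(ux, uy, uz) {
  c0 <- 0.5 * sqrt(15 / pi)
  ad_cbind(
    ad_cbind(
      ad_cbind(ad_scale(ad_mul(ux, uy), c0),
               ad_scale(ad_mul(uy, uz), c0)),
      ad_cbind(ad_addc(ad_scale(ad_mul(uz, uz), 3 * 0.25 * sqrt(5 / pi)),
                       -0.25 * sqrt(5 / pi)),
               ad_scale(ad_mul(ux, uz), c0))),
    ad_scale(ad_sub(ad_mul(ux, ux), ad_mul(uy, uy)), 0.25 * sqrt(15 / pi)))
}

## ---- forward pass --------------------------------------------------------

# Build the full energy graph for a (possibly batched) system.
#
# Z: atomic numbers; X_node: N x 3 coordinate leaf; pairs: directed edge
# matrix (precomputed from the numeric coordinates); pn: list of parameter
# leaf nodes; cfg: model_config.  Returns per-node scalars and vectors after
# the output blocks plus bookkeeping indices.
forward_graph <- function(Z, X_node, pairs, pn, cfg) {
  N <- length(Z)
  D <- n_spatial(cfg)
  Fd <- cfg$hidden_dim
  E <- nrow(pairs)
  iidx <- pairs[, 1L]; jidx <- pairs[, 2L]
  atomD <- rep(seq_len(N), each = D)              # spatial row -> atom
  eD <- rep(seq_len(E), each = D)                 # edge spatial row -> edge
  rows_of <- function(a) rep((a - 1L) * D, each = D) + rep(seq_len(D), length(a))
  rows_i <- rows_of(iidx); rows_j <- rows_of(jidx)
  e3 <- rep(seq_len(E), each = 3L)
  l1rows_of <- function(a) rep((a - 1L) * D, each = 3L) + rep(1:3, length(a))
  l1_i <- l1rows_of(iidx); l1_j <- l1rows_of(jidx)

  if (any(Z > cfg$max_z))
    stop("atomic number outside embedding table (max_z = ", cfg$max_z, ")")

  ## edge geometry
  Xi <- ad_gather(X_node, iidx); Xj <- ad_gather(X_node, jidx)
  d <- ad_sub(Xj, Xi)                             # E x 3, r_ij = R_j - R_i
  r2 <- ad_rowsum_cols(ad_mul(d, d))
  r <- ad_pow(r2, 0.5)
  u <- ad_mul(d, ad_bcast_cols(ad_pow(r2, -0.5), 3L))
  rbf <- ad_rbf(r, cfg)                           # E x K
  phi <- ad_cosine_cutoff(r, cfg$cutoff)          # E x 1
  phiF <- ad_bcast_cols(phi, Fd)

  ## spatial expansion of the edge direction: l = 1 raw components, plus the
  ## order-2 real harmonics when l_max = 2; (D*E) x 1 then broadcast over F
  u_mat <- if (D == 3L) u else {
    ux <- ad_cols(u, 1L, 1L); uy <- ad_cols(u, 2L, 2L); uz <- ad_cols(u, 3L, 3L)
    ad_cbind(u, ad_sh2_cols(ux, uy, uz))
  }
  u_sp <- ad_vec_rows(u_mat)                      # (D*E) x 1
  u_spF <- ad_bcast_cols(u_sp, Fd)
  u3F <- if (D == 3L) u_spF else
    ad_bcast_cols(ad_vec_rows(u), Fd)             # (3E) x F, l=1 only

  ## embedding block
  hz <- ad_gather(pn$emb_table, Z)                # N x F
  filt <- ad_mul(ad_matmul(rbf, pn$emb_Wnbr), phiF)
  nbr <- ad_scatter(ad_mul(ad_gather(hz, jidx), filt), iidx, N)
  h <- ad_dense(ad_cbind(hz, nbr), pn$emb_Wemb, pn$emb_bemb)
  f <- ad_linear(rbf, pn$emb_Wf, pn$emb_bf)       # E x F
  v <- ad_const(matrix(0, D * N, Fd))

  Mh <- matrix(0, Fd, cfg$n_heads)                # channel -> head map
  dh <- Fd %/% cfg$n_heads
  for (hh in seq_len(cfg$n_heads)) Mh[(hh - 1L) * dh + seq_len(dh), hh] <- 1
  Mh_n <- ad_const(Mh); MhT_n <- ad_const(t(Mh))

  rej_l1 <- function(a) {
    ## vector rejection of (3E x F) spatial rows against the edge axis
    adot <- ad_scatter(ad_mul(a, u3F), e3, E)     # E x F
    ad_sub(a, ad_mul(ad_gather(adot, e3), u3F))
  }

  for (l in seq_len(cfg$n_blocks)) {
    g <- function(nm) pn[[sprintf("bl%d_%s", l, nm)]]
    ## --- edge-fusion attention (activation-scored, no softmax) ---
    q <- ad_linear(h, g("Wq"), g("bq"))
    k <- ad_linear(h, g("Wk"), g("bk"))
    vv <- ad_linear(h, g("Wv"), g("bv"))
    dk <- ad_dense(f, g("Wdk"), g("bdk"))
    dv <- ad_dense(f, g("Wdv"), g("bdv"))
    s <- ad_mul(ad_gather(q, iidx), ad_mul(ad_gather(k, jidx), dk))
    alpha <- ad_silu(ad_matmul(s, Mh_n))          # E x H per-head scores
    alphaF <- ad_matmul(alpha, MhT_n)             # broadcast to channels
    m_edge <- ad_mul(ad_mul(alphaF, phiF),
                     ad_mul(ad_gather(vv, jidx), dv))
    m_i <- ad_scatter(m_edge, iidx, N)            # N x F

    ## --- Scalar2Vec: vector messages + gated residual ---
    du <- ad_dense(m_edge, g("Wdu"), g("bdu"))
    dvv <- ad_dense(m_edge, g("Wdvv"), g("bdvv"))
    mvec_edge <- ad_add(ad_mul(ad_gather(du, eD), u_spF),
                        ad_mul(ad_gather(dvv, eD), ad_gather(v, rows_j)))
    mvec_i <- ad_scatter(mvec_edge, rows_i, D * N)
    gate <- ad_linear(m_i, g("Wvm"), g("bvm"))
    dv_res <- ad_add(mvec_i,
                     ad_mul(ad_gather(gate, atomD),
                            ad_matmul(v, g("Wvgate"))))
    v <- ad_add(v, dv_res)

    ## --- Vec2Scalar: runtime angle -> node, runtime dihedral -> edge ---
    vt <- ad_matmul(v, g("Wt")); vs <- ad_matmul(v, g("Ws"))
    angdot <- ad_scatter(ad_mul(vt, vs), atomD, N)
    dh_res <- ad_add(ad_mul(angdot, ad_linear(m_i, g("Wangle"), g("bangle"))),
                     ad_linear(m_i, g("Wres"), g("bres")))
    ra <- rej_l1(ad_gather(ad_matmul(v, g("Wrt")), l1_i))
    rb <- rej_l1(ad_gather(ad_matmul(v, g("Wrs")), l1_j))
    ddot <- ad_scatter(ad_mul(ra, rb), e3, E)
    df_res <- ad_mul(ddot, ad_dense(f, g("Wdd"), g("bdd")))
    if (cfg$use_improper) {
      ta <- rej_l1(ad_gather(ad_matmul(v, g("Wit")), l1_i))
      tb <- rej_l1(ad_gather(ad_matmul(v, g("Wis")), l1_i))
      idot <- ad_scatter(ad_mul(ta, tb), e3, E)
      df_res <- ad_add(df_res, ad_mul(idot, ad_dense(f, g("Wdi"), g("bdi"))))
    }
    h <- ad_add(h, dh_res)
    f <- ad_add(f, df_res)
  }

  ## --- gated equivariant output blocks ---
  for (ob in 1:2) {
    g <- function(nm) pn[[sprintf("out%d_%s", ob, nm)]]
    vw <- ad_matmul(v, g("Wo1"))
    norm2 <- ad_scatter(ad_mul(vw, vw), atomD, N)
    vnorm <- ad_pow(ad_addc(norm2, 1e-12), 0.5)
    tvec <- ad_dense(ad_cbind(vnorm, h), g("Wo2"), g("bo2"))
    h <- ad_linear(tvec, g("Wo3"), g("bo3"))
    gate <- ad_linear(tvec, g("Wo5"), g("bo5"))
    v <- ad_mul(ad_matmul(v, g("Wo4")), ad_gather(gate, atomD))
  }
  list(h = h, v = v, N = N, D = D, atomD = atomD)
}

param_nodes <- function(params) lapply(params, ad_const)

# Forward pass on one configuration; returns nodes for downstream use.
model_forward <- function(model, config) {
  cfg <- model$config
  nlist <- build_neighbor_list(config, cfg$cutoff)
  X_node <- ad_const(config$coordinates)
  pn <- param_nodes(model$params)
  out <- forward_graph(config$atomic_numbers, X_node, nlist$pairs, pn, cfg)
  c(out, list(X_node = X_node, pn = pn))
}

## ---- property heads ------------------------------------------------------

#' Predict the total potential energy
#'
#' Sum over atoms of the final one-dimensional scalar embedding, kcal/mol.
#'
#' @param model an [rgc_model()].
#' @param config an [atomic_configuration()].
#' @return scalar energy.
#' @export
predict_energy <- function(model, config) {
  fw <- model_forward(model, config)
  model_scale(model) * ad_value(ad_sum(fw$h))[1L] + model_shift(model)
}

#' Predict energy and energy-conserving forces
#'
#' Forces are the exact negative gradient of the predicted energy with
#' respect to the coordinates (reverse-mode differentiation), kcal/mol/A.
#'
#' @inheritParams predict_energy
#' @return list with `energy` and `forces` (N x 3).
#' @export
predict_energy_forces <- function(model, config) {
  fw <- model_forward(model, config)
  E <- ad_sum(fw$h)
  gX <- ad_grad(E, fw$X_node)[[1L]]
  sc <- model_scale(model)
  list(energy = sc * ad_value(E)[1L] + model_shift(model),
       forces = -sc * ad_value(gX))
}

#' @rdname predict_energy_forces
#' @export
predict_forces <- function(model, config) {
  predict_energy_forces(model, config)$forces
}

#' Model as a potential function for the MD driver
#' @param model an [rgc_model()].
#' @return `function(config) -> list(energy, forces)`.
#' @export
make_model_potential <- function(model) {
  force(model)
  function(config) predict_energy_forces(model, config)
}

center_of_mass <- function(config) {
  m <- config_masses(config)
  colSums(config$coordinates * m) / sum(m)
}

#' Predict the molecular dipole magnitude
#'
#' `mu = | sum_i v_i^L + h_i^L (r_i - r_c) |` with r_c the center of mass;
#' translation invariant and rotation invariant (magnitude of an equivariant
#' vector).
#'
#' @inheritParams predict_energy
#' @return scalar dipole magnitude (model units).
#' @export
predict_dipole <- function(model, config) {
  fw <- model_forward(model, config)
  h <- ad_value(fw$h)                       # N x 1
  vfull <- ad_value(fw$v)                   # (D N) x 1
  D <- fw$D; N <- fw$N
  vl1 <- t(vapply(seq_len(N), function(i) vfull[(i - 1L) * D + 1:3, 1L],
                  numeric(3)))
  rc <- center_of_mass(config)
  vec <- colSums(vl1 + drop(h) * sweep(config$coordinates, 2L, rc))
  sqrt(sum(vec^2))
}

#' Predict the electronic spatial extent
#'
#' `<R^2> = sum_i h_i^L |r_i - r_c|^2`.
#'
#' @inheritParams predict_energy
#' @return scalar.
#' @export
predict_spatial_extent <- function(model, config) {
  fw <- model_forward(model, config)
  rc <- center_of_mass(config)
  d2 <- rowSums(sweep(config$coordinates, 2L, rc)^2)
  sum(drop(ad_value(fw$h)) * d2)
}

#' Predict a generic scalar property
#'
#' Aggregates the final per-node scalar embedding; shares the reduction path
#' of [predict_energy()].
#'
#' @inheritParams predict_energy
#' @return scalar.
#' @export
predict_scalar <- function(model, config) predict_energy(model, config)

## ---- batched forward for training ---------------------------------------

# Concatenate configurations into one block-diagonal system.  Neighbor lists
# are built per frame (no cross-frame pairs), atom indices offset.
build_batch <- function(configs, cutoff) {
  Z <- integer(0); Xs <- list(); pr <- list(); frame_of_atom <- integer(0)
  off <- 0L
  for (k in seq_along(configs)) {
    cf <- configs[[k]]
    nl <- build_neighbor_list(cf, cutoff)
    Z <- c(Z, cf$atomic_numbers)
    Xs[[k]] <- cf$coordinates
    pr[[k]] <- nl$pairs + off
    frame_of_atom <- c(frame_of_atom, rep(k, n_atoms(cf)))
    off <- off + n_atoms(cf)
  }
  list(Z = Z, X = do.call(rbind, Xs), pairs = do.call(rbind, pr),
       frame_of_atom = frame_of_atom, n_frames = length(configs))
}

# Energies per frame and stacked forces for a batch, as tape nodes.
# Returns list(E_frames (n_frames x 1 node), F_node (N x 3 node, negative
# coordinate gradient), X_node, pn).
batch_energy_forces_graph <- function(params, cfg, batch,
                                      need_forces = TRUE) {
  X_node <- ad_const(batch$X)
  pn <- param_nodes(params)
  out <- forward_graph(batch$Z, X_node, batch$pairs, pn, cfg)
  E_frames <- ad_scatter(out$h, batch$frame_of_atom, batch$n_frames)
  res <- list(E_frames = E_frames, X_node = X_node, pn = pn)
  if (need_forces) {
    gX <- ad_grad(ad_sum(out$h), X_node)[[1L]]
    res$F_node <- ad_neg(gX)
  }
  res
}

## ---- checkpoints ---------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A single `.npz` archive holding every named parameter array plus the model
#' configuration serialized as YAML text (stored as a byte array under
#' `__config__`).
#'
#' @param model an [rgc_model()].
#' @param path checkpoint path (`.npz`).
#' @return `path` / an `rgc_model`.
#' @export
save_checkpoint <- function(model, path) {
  cfg_file <- tempfile()
  write_simple_yaml(unclass(model$config), cfg_file)
  txt <- paste(readLines(cfg_file), collapse = "\n")
  unlink(cfg_file)
  arrays <- model$params
  arrays$`__config__` <- as.integer(charToRaw(txt))
  arrays$`__calibration__` <- c(model_scale(model), model_shift(model))
  write_npz(arrays, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  arrays <- read_npz(path)
  bytes <- arrays$`__config__`
  arrays$`__config__` <- NULL
  calib <- arrays$`__calibration__` %||% c(1, 0)
  arrays$`__calibration__` <- NULL
  tmp <- tempfile()
  writeLines(rawToChar(as.raw(bytes)), tmp)
  y <- read_simple_yaml(tmp)
  unlink(tmp)
  cfg <- model_config(n_blocks = y$n_blocks, hidden_dim = y$hidden_dim,
                      l_max = y$l_max, cutoff = y$cutoff, n_rbf = y$n_rbf,
                      n_heads = y$n_heads, activation = y$activation,
                      use_improper = isTRUE(y$use_improper), head = y$head,
                      max_z = y$max_z)
  params <- lapply(arrays, function(a) if (is.matrix(a)) a else
    matrix(a, nrow = 1L))
  structure(list(config = cfg, params = params,
                 output_scale = calib[1], output_shift = calib[2]),
            class = "rgc_model")
}
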