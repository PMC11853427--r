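#' Label-encode a residue sequence
#'
#' The 20 standard one-letter codes map, in alphabetical order, to the
#' integers 1..20; every other character (X, B, Z, ...) maps to 21. Index 0
#' is reserved for padding in the embedding table.
#'
#' @param sequence Character string of upper-case one-letter codes.
#' @return Integer vector of tokens in `[1, 21]`.
#' @export
label_encode <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) return(integer(0))
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(chars, RESIDUE_ALPHABET[1:20])
  idx[is.na(idx)] <- 21L
  as.integer(idx)
}

# --- residual 1D convolutional local encoder -------------------------------

#' Initialize local-encoder parameters
#'
#' Embedding table (vocabulary 22: padding + 20 residues + "other") followed
#' by three same-length 1-D convolutions with kernel widths 3, 5 and 7
#' (paddings 1, 2, 3), ReLU after each convolution, and residual skips after
#' the second and third layers.
#'
#' @param dim Channel width (1024 in the full architecture).
#' @param seed Integer seed for reproducible initialization.
#' @return Parameter list (class `local_encoder_params`).
#' @export
local_encoder_init <- function(dim = 1024L, seed = 1L) {
  set.seed(seed)
  mk_conv <- function(k) {
    list(W = matrix(rnorm(k * dim * dim, sd = sqrt(2 / (k * dim))), k * dim, dim),
         b = numeric(dim), k = k)
  }
  structure(list(
    dim = as.integer(dim),
    emb = matrix(rnorm(22 * dim, sd = 0.1), 22, dim),
    conv3 = mk_conv(3L), conv5 = mk_conv(5L), conv7 = mk_conv(7L)
  ), class = "local_encoder_params")
}

conv1d_cols <- function(X, k) {
  L <- nrow(X); d <- ncol(X); p <- (k - 1L) %/% 2L
  Xp <- rbind(matrix(0, p, d), X, matrix(0, p, d))
  do.call(cbind, lapply(seq_len(k), function(u) Xp[u:(u + L - 1L), , drop = FALSE]))
}

conv1d_forward <- function(X, layer) {
  cols <- conv1d_cols(X, layer$k)
  z <- cols %*% layer$W
  z <- sweep(z, 2, layer$b, "+")
  list(z = z, cols = cols)
}

conv1d_backward <- function(dz, cache, layer, L) {
  d <- ncol(dz); k <- layer$k; p <- (k - 1L) %/% 2L
  dW <- crossprod(cache$cols, dz)
  db <- colSums(dz)
  dcols <- dz %*% t(layer$W)
  dXp <- matrix(0, L + 2L * p, d)
  for (u in seq_len(k)) {
    idx <- u:(u + L - 1L)
    dXp[idx, ] <- dXp[idx, ] + dcols[, ((u - 1L) * d + 1L):(u * d), drop = FALSE]
  }
  list(dX = dXp[(p + 1L):(p + L), , drop = FALSE], dW = dW, db = db)
}

#' Local sequence encoding of a token sequence
#'
#' Embedding lookup followed by the residual convolutional stack:
#' `a = relu(conv3(e))`, `b = relu(conv5(a)) + e`, `c = relu(conv7(b)) + b`.
#'
#' @param tokens Integer tokens in `[1, 21]` (see [label_encode()]).
#' @param params A `local_encoder_params`.
#' @param keep_cache Keep intermediates for the backward pass.
#' @return `L x dim` matrix (with a `cache` attribute when requested).
#' @export
local_encode <- function(tokens, params, keep_cache = FALSE) {
  L <- length(tokens)
  if (L == 0L) stop("empty token sequence")
  e <- params$emb[tokens + 1L, , drop = FALSE]
  f3 <- conv1d_forward(e, params$conv3)
  a <- pmax(f3$z, 0)
  f5 <- conv1d_forward(a, params$conv5)
  b <- pmax(f5$z, 0) + e
  f7 <- conv1d_forward(b, params$conv7)
  cc <- pmax(f7$z, 0) + b
  if (keep_cache) {
    attr(cc, "cache") <- list(tokens = tokens, e = e, a = a, b = b,
                              f3 = f3, f5 = f5, f7 = f7)
  }
  cc
}

local_encode_backward <- function(dC, cache, params) {
  L <- nrow(dC)
  dz7 <- dC * (cache$f7$z > 0)
  bw7 <- conv1d_backward(dz7, cache$f7, params$conv7, L)
  db_ <- dC + bw7$dX
  dz5 <- db_ * (cache$f5$z > 0)
  bw5 <- conv1d_backward(dz5, cache$f5, params$conv5, L)
  da <- bw5$dX
  de <- db_
  dz3 <- da * (cache$f3$z > 0)
  bw3 <- conv1d_backward(dz3, cache$f3, params$conv3, L)
  de <- de + bw3$dX
  demb <- matrix(0, 22L, params$dim)
  agg <- rowsum(de, group = cache$tokens + 1L)
  demb[as.integer(rownames(agg)), ] <- agg
  list(emb = demb,
       conv3 = list(W = bw3$dW, b = bw3$db),
       conv5 = list(W = bw5$dW, b = bw5$db),
       conv7 = list(W = bw7$dW, b = bw7$db))
}

# --- global embedding providers --------------------------------------------

hash_string <- function(s) {
  ints <- utf8ToInt(s)
  h <- 0
  for (v in ints) h <- (h * 31 + v) %% 1073741789
  h
}

#' Deterministic stand-in embedding provider
#'
#' Emulates a pretrained protein language model's per-residue output with
#' seeded pseudorandom 1024-dim vectors: a position-and-sequence keyed noise
#' component plus an additive residue-type component, so two positions with
#' different residue types always embed differently. Fully deterministic for
#' a fixed sequence and seed; no external model or network access.
#'
#' @param seed Integer seed.
#' @param dim Embedding dimension (1024 to match the real provider).
#' @return An embedding provider: list with `name`, `dim`, `embed(sequence)`.
#' @export
stub_embedding_provider <- function(seed = 0L, dim = 1024L) {
  dim <- as.integer(dim)
  type_vecs <- matrix(0, 21L, dim)
  for (t in 1:21) {
    set.seed((seed * 7919 + t * 104729) %% 2147483629)
    type_vecs[t, ] <- rnorm(dim)
  }
  embed <- function(sequence) {
    tokens <- label_encode(sequence)
    L <- length(tokens)
    out <- matrix(0, L, dim)
    h <- hash_string(sequence)
    for (i in seq_len(L)) {
      set.seed((h * 31 + i * 6151 + seed * 524287) %% 2147483629)
      out[i, ] <- 0.5 * rnorm(dim) + type_vecs[tokens[i], ]
    }
    out
  }
  list(name = "stub", dim = dim, embed = embed)
}

#' ProtT5-style provider placeholder
#'
#' The real pretrained provider is an optional external dependency; this
#' constructor documents the contract and errors with guidance.
#' @param model_path Path to exported per-residue embeddings or model assets.
#' @export
prott5_embedding_provider <- function(model_path = NULL) {
  if (is.null(model_path) || !file.exists(model_path)) {
    stop("ProtT5 provider unavailable: supply precomputed embeddings via ",
         "'model_path', or use stub_embedding_provider() for a deterministic ",
         "stand-in.", call. = FALSE)
  }
  # precomputed container: RDS mapping sequence -> L x 1024 matrix
  store <- readRDS(model_path)
  list(name = "prott5", dim = 1024L, embed = function(sequence) {
    m <- store[[sequence]]
    if (is.null(m)) stop("no precomputed embedding for this sequence")
    m
  })
}

#' Global embeddings for a sequence
#' @param sequence Character string.
#' @param provider An embedding provider.
#' @return `L x dim` matrix.
#' @export
global_embeddings <- function(sequence, provider) {
  m <- provider$embed(sequence)
  if (nrow(m) != nchar(sequence))
    stop("provider returned ", nrow(m), " rows for ", nchar(sequence), " residues")
  m
}

#' Assemble the vertex feature matrix
#'
#' Fixed-order concatenation `[local | global | physchem]`; any block may be
#' `NULL` (ablation variants), shrinking the vertex dimension accordingly.
#' With the default 1024-dim blocks the result is `L x 2084`.
#'
#' @param local,global_,physchem Per-residue blocks with equal row counts.
#' @return Row-wise concatenated matrix.
#' @export
assemble_vertex_features <- function(local, global_, physchem) {
  blocks <- Filter(Negate(is.null), list(local = local, global_ = global_,
                                         physchem = physchem))
  if (length(blocks) == 0L) stop("no feature blocks supplied")
  L <- unique(vapply(blocks, nrow, integer(1)))
  if (length(L) != 1L)
    stop("row mismatch across blocks: ",
         paste(vapply(blocks, nrow, integer(1)), collapse = " vs "))
  do.call(cbind, unname(blocks))
}
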