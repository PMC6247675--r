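# Shared fixtures, built once per test run, and independent brute-force
# oracles for the network features.

.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

SMALL_SHAPE <- c(32L, 36L, 30L)
SMALL_SPEC <- patch_spec(8, 9, 10)

small_template <- function() fixture("template", generate_template(SMALL_SHAPE, 1))

small_grid <- function() fixture("grid",
  build_patch_grid(SMALL_SHAPE, SMALL_SPEC, small_template()$mask, 0.10))

small_boxes <- function(n = 2L)
  utils::head(fixture("boxes",
    pick_affected_boxes(small_grid(), small_template(), 4L, "L")), n)

# 10 + 10 subjects, two lesioned boxes in the left hemisphere
small_cohort <- function() fixture("cohort",
  generate_cohort(phantom_config(SMALL_SHAPE, n_per_class = 10L,
                                 effect_size = 0.6, noise_sd = 0.05,
                                 bias_scale = 0.05,
                                 affected_boxes = small_boxes(2L), seed = 11)))

small_layers <- function() fixture("small_layers", {
  co <- small_cohort()
  lapply(seq_along(co$volumes), function(i)
    build_layer(co$volumes[[i]], small_grid(), correlation_config(),
                co$subject_ids[i]))
})

# wrap a bare weight matrix as a layer
make_layer <- function(W, id = NA_character_,
                       config = correlation_config()) {
  structure(list(W = W, subject_id = id, N = ncol(W), config = config),
            class = "layer_network")
}

# random symmetric thresholded weight matrix
random_W <- function(N, density = 0.5, signed = FALSE) {
  W <- matrix(0, N, N)
  ut <- upper.tri(W)
  w <- stats::runif(sum(ut))
  w[stats::runif(sum(ut)) > density] <- 0
  if (signed) w <- w * sample(c(-1, 1), length(w), replace = TRUE)
  W[ut] <- w
  W <- W + t(W)
  colnames(W) <- rownames(W) <- sprintf("n%02d", seq_len(N))
  W
}

# synthetic layers in which one node's edge weight separates the classes
separable_layers <- function(n_per_class = 10L, N = 6L, seed = 1L) {
  set.seed(seed)
  mk <- function(w12) {
    W <- matrix(0, N, N, dimnames = list(sprintf("n%02d", 1:N),
                                         sprintf("n%02d", 1:N)))
    W[1, 2] <- W[2, 1] <- w12
    W[3, 4] <- W[4, 3] <- stats::runif(1, 0.4, 0.6)   # uninformative edge
    W
  }
  layers <- c(lapply(seq_len(n_per_class), function(i)
                make_layer(mk(stats::runif(1, 0.85, 0.95)))),
              lapply(seq_len(n_per_class), function(i)
                make_layer(mk(stats::runif(1, 0.35, 0.45)))))
  labels <- factor(rep(c("control", "disease"), each = n_per_class))
  list(layers = layers, labels = labels)
}

# ---- brute-force oracles: explicit loops over the defining sums ----

oracle_strength <- function(W) {
  N <- nrow(W)
  s <- numeric(N)
  for (i in 1:N) for (j in 1:N) s[i] <- s[i] + W[i, j]
  s
}

oracle_ipr <- function(W) {
  N <- nrow(W)
  s <- oracle_strength(W)
  Y <- numeric(N)
  for (i in 1:N) {
    if (s[i] == 0) next
    for (j in 1:N) Y[i] <- Y[i] + (W[i, j] / s[i])^2
  }
  Y
}

oracle_degree <- function(W) {
  N <- nrow(W)
  k <- integer(N)
  for (i in 1:N) for (j in 1:N) if (W[i, j] != 0) k[i] <- k[i] + 1L
  k
}

# conditional mean of `vals` at each node's own group value (Kronecker delta
# sum); group 0 -> 0
oracle_cond_mean <- function(vals, groups) {
  N <- length(vals)
  out <- numeric(N)
  for (i in 1:N) {
    if (groups[i] == 0) next
    tot <- 0; nk <- 0L
    for (j in 1:N) if (groups[j] == groups[i]) { tot <- tot + vals[j]; nk <- nk + 1L }
    out[i] <- tot / nk
  }
  out
}

oracle_aggregate <- function(Ws) {
  N <- nrow(Ws[[1L]])
  A <- matrix(0L, N, N)
  for (a in seq_along(Ws)) for (i in 1:N) for (j in 1:N)
    if (i != j && abs(Ws[[a]][i, j]) > 0) A[i, j] <- 1L
  A
}

# all eight per-node features of every layer, by loops
oracle_all_features <- function(Ws) {
  A <- oracle_aggregate(Ws)
  N <- nrow(A)
  km <- integer(N)
  for (i in 1:N) for (j in 1:N) km[i] <- km[i] + A[i, j]
  lapply(Ws, function(W) {
    s <- oracle_strength(W)
    Y <- oracle_ipr(W)
    k <- oracle_degree(W)
    list(strength = s, ipr = Y,
         strengthk = oracle_cond_mean(s, k),
         iprk = oracle_cond_mean(Y, k),
         mstrength = km / (N - 1) * s,
         mipr = km / (N - 1) * Y,
         mstrengthk = oracle_cond_mean(s, km),
         miprk = oracle_cond_mean(Y, km))
  })
}

# exact binomial upper tail by summation
oracle_binom_tail <- function(c, n, p) {
  if (c <= 0) return(1)
  tot <- 0
  for (x in c:n) tot <- tot + stats::dbinom(x, n, p)
  tot
}
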