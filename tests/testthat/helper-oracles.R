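# Independent oracles used by several test files.

# Brute-force Benjamini-Hochberg step-up: for each p, q is the smallest
# adjusted value over all p_j >= p_i (sorted tail minimum), computed
# directly from the definition without vectorised tricks.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (k in seq_len(m)) {
    q[k] <- min(1, min(ps[k:m] * m / (k:m)))
  }
  q[order(o)]
}

# Brute-force per-pixel co-occurrence: explicit double loop.
cooc_oracle <- function(target_grid, reference_grid) {
  dual <- 0L; total <- 0L
  for (r in seq_len(nrow(reference_grid))) {
    for (c in seq_len(ncol(reference_grid))) {
      if (reference_grid[r, c]) {
        total <- total + 1L
        if (target_grid[r, c]) dual <- dual + 1L
      }
    }
  }
  dual / total
}

# Enumerate the reduced Visium lattice positions by direct looping.
lattice_oracle <- function(grid_rows, grid_cols) {
  n <- 0L
  for (r in seq_len(grid_rows) - 1L) {
    for (c in seq_len(grid_cols) - 1L) {
      if (r %% 2L == c %% 2L) n <- n + 1L
    }
  }
  n
}

# Small spec so stitching tests stay fast.
small_spec <- function(seed = 1L) {
  fixture_spec(seed = seed, grid_rows = 4L, grid_cols = 6L, n_genes = 12L,
               image_shape = c(32L, 48L), noise_sd = 1)
}

# all permutations of 1..n (tiny n only)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in combinat_perms(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, ifelse(rest >= i, rest + 1L, rest))
    }
  }
  out
}

# Toy QC matrix exercising all three boundary rules at once:
#  - 6 support cells expressing every gene (keep genes above the 5-cell bar)
#  - C200 / C199: exactly 200 vs 199 expressed genes
#  - CM_keep / CM_drop: mito UMI fraction exactly 0.10 vs 0.11
#  - H4 / H5: expressed in exactly 4 vs 5 surviving cells
qc_fixture <- function() {
  genes <- c(sprintf("G%03d", 1:250), "MT-ND1", "H4", "H5")
  cells <- c(paste0("S", 1:6), "C200", "C199", "CM_keep", "CM_drop")
  m <- matrix(0, length(genes), length(cells), dimnames = list(genes, cells))
  m[, paste0("S", 1:6)] <- 1
  m["H4", paste0("S", 5:6)] <- 0   # H4 only in S1..S4
  m["H5", "S6"] <- 0               # H5 only in S1..S5
  m[sprintf("G%03d", 1:200), "C200"] <- 1
  m[sprintf("G%03d", 1:199), "C199"] <- 1
  m[sprintf("G%03d", 1:225), "CM_keep"] <- 4    # 900 UMI + 100 mito = 0.10
  m["MT-ND1", "CM_keep"] <- 100
  m[sprintf("G%03d", 1:222), "CM_drop"] <- 4    # 890 UMI + 110 mito = 0.11
  m["G223", "CM_drop"] <- 2
  m["MT-ND1", "CM_drop"] <- 110
  m
}

# counts with genes planted at OR ~32.3, 13.5 and 1.0 between groups
biased_fixture <- function() {
  genes <- c("PLANT30", "PLANT13", "FLAT")
  m <- matrix(0, 3, 200, dimnames = list(genes, sprintf("c%03d", 1:200)))
  a <- 1:100; b <- 101:200
  m["PLANT30", a[1:50]] <- 1   # 0.50 vs 0.03: OR = 1 / 0.0309 = 32.3
  m["PLANT30", b[1:3]] <- 1
  m["PLANT13", a[1:60]] <- 1   # 0.60 vs 0.10: OR = 13.5
  m["PLANT13", b[1:10]] <- 1
  m["FLAT", c(a[1:40], b[1:40])] <- 1
  list(counts = m, groups = factor(rep(c("proximal", "distal"), each = 100),
                                   levels = c("proximal", "distal")))
}

random_affine <- function() {
  repeat {
    v <- stats::runif(6, -1, 1)
    v[5:6] <- stats::runif(2, -50, 50)
    if (abs(v[1] * v[4] - v[2] * v[3]) > 0.2) {
      return(affine2d(v[1], v[2], v[3], v[4], v[5], v[6]))
    }
  }
}
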