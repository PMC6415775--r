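# Shared fixtures, built in code.

tiny_counts <- function() {
  tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    taxonA = c(5L, 1L, 2L),
    taxonB = c(0L, 3L, 2L),
    taxonC = c(3L, 0L, 2L)
  )
}

tiny_taxonomy <- function() {
  tibble::tibble(
    feature_id = c("taxonA", "taxonB", "taxonC"),
    kingdom = "Bacteria",
    phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes"),
    family = c("F1", "F1", "F2"),
    genus = c("Blautia", "Blautia", "Bacteroides")
  )
}

# Random Dirichlet-multinomial count tibble with a planted partition.
random_dm_counts <- function(n, s, depth, k = 1, seed = 1, sep = 10) {
  withr::with_seed(seed, {
    alpha <- matrix(stats::runif(k * s, 0.2, 2), k, s)
    if (k > 1) {
      for (j in seq_len(k)) {
        dom <- ((j - 1) * floor(s / k) + 1):min(j * floor(s / k), s)
        alpha[j, dom] <- alpha[j, dom] * sep
      }
    }
    z <- sample.int(k, n, replace = TRUE)
    m <- matrix(0L, n, s, dimnames = list(paste0("s", seq_len(n)),
                                          paste0("t", seq_len(s))))
    for (i in seq_len(n)) {
      g <- stats::rgamma(s, alpha[z[i], ])
      m[i, ] <- as.integer(stats::rmultinom(1, depth, g / sum(g)))
    }
    list(counts = dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                                   tibble::as_tibble(m)),
         z = z, alpha = alpha)
  })
}

# Independent single-component Dirichlet-multinomial fit (Minka fixed
# point, unweighted) used as an oracle against the K = 1 EM path.
oracle_dm_fit <- function(X, iters = 500, tol = 1e-12) {
  n <- rowSums(X)
  alpha <- colMeans(X / n) * 10 + 1e-3
  for (it in seq_len(iters)) {
    A <- sum(alpha)
    num <- colSums(digamma(sweep(X, 2, alpha, "+"))) - nrow(X) * digamma(alpha)
    den <- sum(digamma(n + A)) - nrow(X) * digamma(A)
    new <- alpha * num / den
    new[num <= 0] <- 1e-8
    if (max(abs(new - alpha) / pmax(alpha, 1e-8)) < tol) {
      alpha <- new
      break
    }
    alpha <- new
  }
  alpha
}

# Adjusted Rand index between two label vectors.
ari <- function(a, b) {
  tab <- table(a, b)
  sc <- sum(choose(tab, 2))
  sr <- sum(choose(rowSums(tab), 2))
  scol <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  e <- sr * scol / choose(n, 2)
  (sc - e) / ((sr + scol) / 2 - e)
}
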