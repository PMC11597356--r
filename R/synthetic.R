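# Synthetic-data generator.  Emulates the statistical structure the
# pipeline assumes -- correlated fingerprint/descriptor matrices with
# degenerate columns, and a sparse linear pIC50 response with known active
# features -- so that every stage (filters, selectors, nested CV,
# randomization, AD, screening) is testable with a known ground truth.

#' Specify a synthetic QSAR dataset
#'
#' @param n Number of compounds.
#' @param p Number of base features (informative + noise), excluding the
#'   injected degenerate columns.
#' @param k_informative Number of features carrying signal.
#' @param beta Effect size per informative feature (recycled), default 1.
#' @param noise_sd Gaussian noise sd on the response; alternatively give
#'   \code{r_star2} and the noise sd is derived.
#' @param r_star2 Target generative signal fraction
#'   Var(signal)/(Var(signal)+noise^2); used when \code{noise_sd} is NULL.
#' @param feature_kind "continuous" descriptors or "binary" fingerprint
#'   bits.
#' @param n_constant,n_quasi,n_redundant Number of injected constant,
#'   quasi-constant (single rare off-value) and redundant (noisy copy,
#'   |r| > 0.9) columns.
#' @param block_corr Exchangeable correlation within blocks of noise
#'   features, in \[0, 1); informative features are mutually independent so
#'   the generative signal fraction stays exact.
#' @param block_size Noise-block width, default 10.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(n, p, k_informative, beta = 1, noise_sd = NULL,
                           r_star2 = NULL, feature_kind = c("continuous", "binary"),
                           n_constant = 0, n_quasi = 0, n_redundant = 0,
                           block_corr = 0, block_size = 10, seed = 1) {
  feature_kind <- match.arg(feature_kind)
  if (k_informative > p) {
    stop_qsar("k_informative cannot exceed p", "qsarnest_spec_error")
  }
  if (block_corr < 0 || block_corr >= 1) {
    stop_qsar("block_corr must lie in [0, 1)", "qsarnest_spec_error")
  }
  if (is.null(noise_sd) && is.null(r_star2)) noise_sd <- 1
  structure(list(
    n = n, p = p, k_informative = k_informative,
    beta = rep_len(beta, k_informative), noise_sd = noise_sd,
    r_star2 = r_star2, feature_kind = feature_kind,
    n_constant = n_constant, n_quasi = n_quasi, n_redundant = n_redundant,
    block_corr = block_corr, block_size = block_size, seed = seed
  ), class = "synthetic_spec")
}

#' Generate the feature matrix of a synthetic dataset
#'
#' Continuous features are standard normal with exchangeable correlation
#' \code{block_corr} within blocks of noise features; binary features are
#' thresholded latent gaussians with marginal on-bit frequencies drawn in
#' \[0.05, 0.6\] (sparse structural keys).  Injected degenerate columns --
#' constant, quasi-constant and redundant near-copies -- carry prefixed
#' names (\code{const_}, \code{quasi_}, \code{redundant_}) so filter tests
#' can check recovery.  Informative columns are named \code{inf_1} ... and
#' are mutually independent.
#'
#' @param spec A [synthetic_spec()].
#' @return A \code{feature_matrix} with attribute \code{"truth"} (the
#'   informative feature names) reachable via \code{attr}.
#' @export
gen_features <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    k <- spec$k_informative
    n <- spec$n
    n_noise <- spec$p - k
    latent <- matrix(stats::rnorm(n * spec$p), n, spec$p)
    if (spec$block_corr > 0 && n_noise > 0) {
      blocks <- rep(seq_len(ceiling(n_noise / spec$block_size)),
                    each = spec$block_size, length.out = n_noise)
      shared <- matrix(stats::rnorm(n * max(blocks)), n)
      rho <- spec$block_corr
      latent[, k + seq_len(n_noise)] <-
        sqrt(rho) * shared[, blocks] +
        sqrt(1 - rho) * latent[, k + seq_len(n_noise)]
    }
    colnames(latent) <- c(
      if (k > 0) paste0("inf_", seq_len(k)),
      if (n_noise > 0) paste0("noise_", seq_len(n_noise))
    )

    if (spec$feature_kind == "binary") {
      freq <- stats::runif(spec$p, 0.05, 0.6)
      values <- sweep(latent, 2, stats::qnorm(1 - freq), ">") * 1L
      attr(values, "bit_freq") <- freq
    } else {
      values <- latent
    }

    extras <- list()
    if (spec$n_constant > 0) {
      extras$const <- matrix(0, n, spec$n_constant,
                             dimnames = list(NULL, paste0("const_", seq_len(spec$n_constant))))
    }
    if (spec$n_quasi > 0) {
      q <- matrix(0, n, spec$n_quasi,
                  dimnames = list(NULL, paste0("quasi_", seq_len(spec$n_quasi))))
      for (j in seq_len(spec$n_quasi)) {
        q[sample.int(n, max(1L, floor(0.01 * n))), j] <- 1
      }
      extras$quasi <- q
    }
    if (spec$n_redundant > 0) {
      parents <- sample(colnames(latent), spec$n_redundant, replace = TRUE)
      r <- vapply(seq_len(spec$n_redundant), function(j) {
        if (spec$feature_kind == "binary") {
          # flip a few bits of the parent: high but imperfect agreement
          col <- values[, parents[j]]
          flip <- stats::runif(n) < 0.005
          as.numeric(ifelse(flip, 1 - col, col))
        } else {
          values[, parents[j]] + stats::rnorm(n, 0, 0.3)
        }
      }, numeric(n))
      colnames(r) <- paste0("redundant_", seq_len(spec$n_redundant),
                            "_of_", parents)
      extras$redundant <- r
    }

    out <- do.call(cbind, c(list(values), unname(extras)))
    fm <- feature_matrix(out, kind = spec$feature_kind)
    attr(fm, "truth") <- if (k > 0) paste0("inf_", seq_len(k)) else character(0)
    attr(fm, "bit_freq") <- attr(values, "bit_freq")
    fm
  })
}

#' Generate the response of a synthetic dataset
#'
#' \code{y = intercept + sum(beta_j x_j) + N(0, noise_sd)}, affinely mapped
#' to mean 6 and sd 1.5 so that values span a realistic pIC50 range
#' (roughly 3 to 9, matching the dynamic range of IC50 assays from
#' millimolar to sub-nanomolar).  The affine map preserves the generative
#' signal fraction \code{r_star2}, which is recorded along with the active
#' feature set.
#'
#' @param fm Feature matrix from [gen_features()].
#' @param spec The same [synthetic_spec()].
#' @return List: \code{y}, \code{truth} (active feature names),
#'   \code{r_star2} (implied generative R-squared), \code{noise_sd}.
#' @export
gen_response <- function(fm, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  X <- fm_values(fm)
  truth <- attr(fm, "truth")
  k <- length(truth)
  if (spec$feature_kind == "binary") {
    freq <- attr(fm, "bit_freq")[seq_len(k)]
    var_signal <- sum(spec$beta^2 * freq * (1 - freq))
    mean_signal <- sum(spec$beta * freq)
  } else {
    var_signal <- sum(spec$beta^2)
    mean_signal <- 0
  }
  noise_sd <- spec$noise_sd %||%
    sqrt(var_signal * (1 - spec$r_star2) / spec$r_star2)
  r_star2 <- var_signal / (var_signal + noise_sd^2)

  y_raw <- with_seed(spec$seed + 1L, {
    drop(X[, truth, drop = FALSE] %*% spec$beta) +
      stats::rnorm(spec$n, 0, noise_sd)
  })
  total_sd <- sqrt(var_signal + noise_sd^2)
  b <- if (total_sd > 0) 1.5 / total_sd else 1
  a <- 6 - b * mean_signal
  list(y = a + b * y_raw, truth = truth, r_star2 = r_star2,
       noise_sd = noise_sd)
}

#' Generate a raw activity-table fixture for curation tests
#'
#' A small hand-designed table of real (simple) chemistry exercising every
#' curation rule: a triplicated structure written as three different
#' SMILES strings, an acid/sodium-salt pair, an unparsable SMILES, a
#' non-positive IC50 and a blank IC50, padded with unique druglike-ish
#' molecules.  Row order is shuffled by \code{seed}.  The returned
#' manifest records the expected post-curation outcome.
#'
#' @param seed Integer seed for the row shuffle.
#' @param path Optional CSV path to write the table to.
#' @return List with \code{table} (data frame: id, smiles, ic50_nM) and
#'   \code{manifest} (expected counts and merged IC50s).
#' @export
gen_curation_fixture <- function(seed = 1, path = NULL) {
  dup_trio <- data.frame(
    id = c("dup1", "dup2", "dup3"),
    smiles = c("OC(=O)c1ccccc1", "c1ccccc1C(O)=O", "C(=O)(O)c1ccccc1"),
    ic50_nM = c(1, 10, 100)
  )
  salt_pair <- data.frame(
    id = c("acid", "salt"),
    smiles = c("CC(=O)O", "CC(=O)[O-].[Na+]"),
    ic50_nM = c(50, 200)
  )
  bad_rows <- data.frame(
    id = c("badsmiles", "zeroic50", "blankic50"),
    smiles = c("this_is_not_smiles", "CCO", "CCN"),
    ic50_nM = c(10, 0, NA)
  )
  unique_rows <- data.frame(
    id = sprintf("cmp%02d", 1:22),
    smiles = c(
      "c1ccncc1", "c1ccc2ccccc2c1", "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
      "CC(=O)Oc1ccccc1C(=O)O", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
      "NCCc1ccc(O)c(O)c1", "CCOC(=O)c1ccccc1", "Clc1ccc(Cl)cc1",
      "OCC(O)CO", "CCCCCCCCO", "Cc1ccccc1C", "COc1ccc(CCN)cc1",
      "CC(N)Cc1ccccc1", "OC(=O)CCC(=O)O", "Nc1ccc(cc1)S(N)(=O)=O",
      "CC(C)(C)c1ccc(O)cc1", "c1ccc(cc1)c1ccccc1", "OCCOCCO",
      "CC1CCCCC1", "Fc1ccc(F)cc1", "CCN(CC)CC", "CC(=O)Nc1ccc(O)cc1"
    ),
    ic50_nM = c(5, 12, 45, 78, 120, 230, 340, 560, 890, 1200, 2500, 4100,
                6000, 9800, 15000, 25000, 48000, 90000, 150000, 320000,
                700000, 1200000)
  )
  tab <- rbind(dup_trio, salt_pair, bad_rows, unique_rows)
  tab <- with_seed(seed, tab[sample.int(nrow(tab)), , drop = FALSE])
  rownames(tab) <- NULL
  manifest <- list(
    n_in = nrow(tab), n_out = 24L, n_dropped = 3L, n_merged_structures = 2L,
    merged_ic50 = c(benzoic_acid = 10, acetic_acid = 125),
    acid_salt_ids = c("acid", "salt")
  )
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  }
  list(table = tab, manifest = manifest)
}
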