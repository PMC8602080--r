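# Independent oracles used across the suite. Each deliberately uses a
# different code path from the implementation it checks (exhaustive
# enumeration, closed forms, brute-force counting).

# Exhaustive-enumeration scanner: list every (c1,c2,h1,h2) index tuple
# satisfying the grammar, then apply the stated left-to-right
# non-overlap reduction (smallest c1, then smallest b, then c, then a;
# resume after the terminal H; truncated candidates only at a c1 with no
# full completion).
oracle_scan <- function(sequence, grammar, allow_truncated = FALSE) {
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  n <- length(ch)
  cs <- which(ch == "C"); hs <- which(ch == "H")
  quads <- list(); triples <- list()
  for (c1 in cs) for (c2 in cs[cs > c1]) {
    a <- c2 - c1 - 1
    if (!a %in% grammar$a_allowed) next
    for (h1 in hs[hs > c2]) {
      b <- h1 - c2 - 1
      if (!b %in% grammar$b_allowed) next
      triples[[length(triples) + 1]] <- c(c1, c2, h1, a, b)
      for (h2 in hs[hs > h1]) {
        cc <- h2 - h1 - 1
        if (!cc %in% grammar$c_allowed) next
        quads[[length(quads) + 1]] <- c(c1, c2, h1, h2, a, b, cc)
      }
    }
  }
  quads <- if (length(quads)) do.call(rbind, quads) else
    matrix(numeric(), 0, 7)
  triples <- if (length(triples)) do.call(rbind, triples) else
    matrix(numeric(), 0, 5)
  out <- list()
  cursor <- 1
  repeat {
    fc1 <- quads[quads[, 1] >= cursor, 1]
    tc1 <- if (allow_truncated) triples[triples[, 1] >= cursor, 1]
           else numeric(0)
    cand_c1 <- sort(unique(c(fc1, tc1)))
    if (length(cand_c1) == 0) break
    advanced <- FALSE
    for (c1 in cand_c1) {
      q <- quads[quads[, 1] == c1, , drop = FALSE]
      if (nrow(q) > 0) {
        q <- q[order(q[, 6], q[, 7], q[, 5]), , drop = FALSE]
        out[[length(out) + 1]] <- c(q[1, ], trunc = 0)
        cursor <- q[1, 4] + 1
        advanced <- TRUE
        break
      }
      if (allow_truncated) {
        t3 <- triples[triples[, 1] == c1, , drop = FALSE]
        if (nrow(t3) > 0) {
          t3 <- t3[order(t3[, 5], t3[, 4]), , drop = FALSE]
          out[[length(out) + 1]] <-
            c(t3[1, 1:3], NA, t3[1, 4:5], NA, trunc = 1)
          cursor <- t3[1, 3] + 1
          advanced <- TRUE
          break
        }
      }
    }
    if (!advanced) break
  }
  if (length(out) == 0)
    return(data.frame(c1 = integer(), c2 = integer(), h1 = integer(),
                      h2 = integer(), a = integer(), b = integer(),
                      cc = integer(), truncated = logical()))
  m <- do.call(rbind, out)
  data.frame(c1 = m[, 1], c2 = m[, 2], h1 = m[, 3], h2 = m[, 4],
             a = m[, 5], b = m[, 6], cc = m[, 7],
             truncated = m[, 8] == 1)
}

# Random protein sequence with boosted C/H frequency so fingers occur.
random_protein <- function(len, p_c = 0.08, p_h = 0.12) {
  letters20 <- zfatlas:::AA_ALPHABET
  probs <- rep((1 - p_c - p_h) / 18, 20)
  probs[letters20 == "C"] <- p_c
  probs[letters20 == "H"] <- p_h
  paste(sample(letters20, len, replace = TRUE, prob = probs),
        collapse = "")
}

# Closed-form balanced one-way REML BLUP from ANOVA mean squares:
# remove environment means, then sigma2_e = MSE, sigma2_l = (MSB-MSE)/n,
# BLUP_i = n*sigma2_l / (n*sigma2_l + sigma2_e) * (line mean deviation).
oracle_balanced_blup <- function(d) {
  env_mean <- tapply(d$y, d$env, mean)
  y_adj <- d$y - env_mean[d$env] + mean(d$y)
  line_mean <- tapply(y_adj, d$line, mean)
  grand <- mean(y_adj)
  n_env <- length(unique(d$env))
  n_line <- length(unique(d$line))
  msb <- n_env * sum((line_mean - grand)^2) / (n_line - 1)
  mse <- sum((y_adj - line_mean[d$line])^2) /
    ((n_line - 1) * (n_env - 1))
  s2l <- max((msb - mse) / n_env, 0)
  shrink <- n_env * s2l / (n_env * s2l + mse)
  blup <- shrink * (line_mean - grand)
  list(blup = blup, var_line = s2l, var_resid = mse)
}

# Haplotype-counting r2 for fully homozygous lines: haplotype
# frequencies are genotype frequencies, D = p11 - p1*q1.
oracle_haplotype_r2 <- function(g1, g2) {
  stopifnot(all(g1 %in% c(0, 2)), all(g2 %in% c(0, 2)))
  h1 <- g1 / 2; h2 <- g2 / 2
  p1 <- mean(h1); p2 <- mean(h2)
  p11 <- mean(h1 == 1 & h2 == 1)
  D <- p11 - p1 * p2
  D^2 / (p1 * (1 - p1) * p2 * (1 - p2))
}

# Column-scan oracle for variant extraction: counts expected markers of
# each type on a deletions-only alignment (reference ungapped).
oracle_variant_count <- function(aln, ref_row) {
  gap <- aln == "-"
  valid <- aln %in% c("A", "C", "G", "T")
  dim(valid) <- dim(aln)
  n_snp <- 0L; n_indel <- 0L
  prev_members <- NULL; in_run <- FALSE
  for (j in seq_len(ncol(aln))) {
    g <- gap[, j]
    if (any(g) && !all(g)) {
      if (!in_run || !identical(prev_members, g)) n_indel <- n_indel + 1L
      in_run <- TRUE; prev_members <- g
    } else {
      in_run <- FALSE; prev_members <- NULL
      obs <- aln[valid[, j] & !g, j]
      if (length(unique(obs)) >= 2) n_snp <- n_snp + 1L
    }
  }
  c(snp = n_snp, indel = n_indel)
}

finger_cols <- c("c1", "c2", "h1", "h2", "a", "b", "cc", "truncated")
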