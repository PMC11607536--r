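# Fixtures built in code and independent reference implementations (oracles)
# used across the suite.

# tiny hand-written panel: 3 samples x 4 SNPs, one missing call
tiny_panel <- function() {
  g <- matrix(c(0L, 1L, 2L, NA,
                2L, 2L, 0L, 1L,
                1L, 0L, 1L, 2L),
              nrow = 3, byrow = TRUE)
  snps <- data.frame(
    snp_id = paste0("rs", 1:4),
    chromosome = c(1L, 1L, 2L, 2L),
    position_bp = c(1000L, 2000L, 500L, 1500L),
    position_cm = c(0.001, 0.002, 0.0005, 0.0015),
    ref = "A", alt = "G"
  )
  samples <- data.frame(sample_id = c("s1", "s2", "s3"),
                        label = c("pop1", "pop1", "pop2"))
  genotype_panel(g, snps, samples)
}

# evenly spaced single-region panel for direct ROH-scanner tests:
# calls is an integer vector (0/1/2/NA), one chromosome unless chrom given
roh_test_snps <- function(n, spacing_cm = 0.5, chromosome = 1L) {
  tibble::tibble(
    snp_id = paste0("m", seq_len(n)),
    chromosome = chromosome,
    position_bp = as.integer(seq_len(n) * 1e5),
    position_cm = (seq_len(n) - 1) * spacing_cm,
    ref = "A", alt = "G"
  )
}

# Independent ROH oracle: a literal, non-incremental transliteration of the
# scan rules. At each cursor it opens a candidate at the next homozygous
# call and re-derives every tally from scratch at each extension step, so
# it shares no code path with call_roh().
roh_oracle <- function(calls, cm, params) {
  hom <- !is.na(calls) & calls %in% c(0L, 2L)
  het <- !is.na(calls) & calls == 1L
  n <- length(calls)
  found <- list()
  cursor <- 1L
  repeat {
    homs_ahead <- which(hom & seq_len(n) >= cursor)
    if (length(homs_ahead) == 0) break
    start <- homs_ahead[1]
    end <- start
    while (end < n) {
      nxt <- end + 1L
      if (het[nxt]) {
        span <- start:nxt
        if (sum(het[span]) > params$max_het_count ||
            sum(het[span]) / (sum(het[span]) + sum(hom[span])) >
              params$max_het_prop) break
      }
      end <- nxt
    }
    last_hom <- max(which(hom & seq_len(n) >= start & seq_len(n) <= end))
    span <- start:last_hom
    len <- cm[last_hom] - cm[start]
    ok <- len > params$min_length_cm && sum(hom[span]) >= params$min_hom_snps
    if (ok) {
      found[[length(found) + 1L]] <- data.frame(
        start_index = start, end_index = last_hom, length_cm = len,
        n_hom = sum(hom[span]), n_het = sum(het[span])
      )
      cursor <- last_hom + 1L
    } else {
      hets_inside <- which(het & seq_len(n) >= start & seq_len(n) <= last_hom)
      if (length(hets_inside) > 0) {
        cursor <- hets_inside[1] + 1L
      } else if (end < n) {
        cursor <- end + 2L   # candidate ended by an immediate het violation
      } else {
        break
      }
    }
  }
  do.call(rbind, found)
}

# Independent f4 oracle: explicit loops, no shared code with f4()
f4_oracle <- function(panel, pop_a, pop_b, pop_c, pop_d) {
  labs <- list(pop_a, pop_b, pop_c, pop_d)
  vals <- c()
  for (j in seq_len(ncol(panel$genotypes))) {
    ps <- numeric(4)
    ok <- TRUE
    for (i in 1:4) {
      rows <- which(panel$samples$label == labs[[i]])
      g <- panel$genotypes[rows, j]
      g <- g[!is.na(g)]
      if (length(g) == 0) { ok <- FALSE; break }
      ps[i] <- sum(g) / (2 * length(g))
    }
    if (ok) vals <- c(vals, (ps[1] - ps[2]) * (ps[3] - ps[4]))
  }
  mean(vals)
}

# panel built directly from per-population allele-frequency quadruples,
# one diploid "population" of clones per column (frequencies exact: 0 or 1
# map to fixed genotypes; 0.5 to one het individual)
panel_from_freqs <- function(freqs) {
  # freqs: matrix n_pops x n_snps with entries in {0, 0.5, 1}
  n_pop <- nrow(freqs)
  n_snp <- ncol(freqs)
  g <- matrix(0L, n_pop, n_snp)
  g[freqs == 0.5] <- 1L
  g[freqs == 1] <- 2L
  snps <- data.frame(
    snp_id = paste0("q", seq_len(n_snp)), chromosome = 1L,
    position_bp = seq_len(n_snp) * 100L,
    position_cm = seq_len(n_snp) * 0.01, ref = "A", alt = "G"
  )
  samples <- data.frame(sample_id = paste0("p", seq_len(n_pop)),
                        label = paste0("pop", seq_len(n_pop)))
  genotype_panel(g, snps, samples)
}

# flat synthetic calibration curve
constant_curve <- function(mu, sigma, cal_bp = 0:2000) {
  cal_curve(cal_bp = cal_bp, c14_age = rep(mu, length(cal_bp)),
            sigma = rep(sigma, length(cal_bp)))
}

# identity curve: mu(t) = t with (near-)zero curve error
identity_curve <- function(cal_bp = 0:3000, sigma = 1e-9) {
  cal_curve(cal_bp = cal_bp, c14_age = cal_bp,
            sigma = rep(sigma, length(cal_bp)))
}
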