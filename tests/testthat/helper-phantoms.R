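# shared fixture builders; everything is generated in code at test time

layout_roles <- function() {
  vapply(default_region_layout(), `[[`, "", "role")
}

# uptake map with all reference blocks at `ref` and the four target lobes
# at `target`
uniform_uptake <- function(target = 1.5, ref = 1.0) {
  u <- as.list(stats::setNames(rep(ref, 9), layout_roles()))
  for (r in c("frontal", "cingulate", "lateral_parietal", "lateral_temporal"))
    u[[r]] <- target
  u
}

# independent brute-force separable-Gaussian oracle evaluated at a single
# voxel (explicit triple loop over kernel offsets, reflect indexing)
dense_smooth_at <- function(x, fwhm_mm, voxel_mm, at) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  w <- dnorm(-r:r, sd = sigma); w <- w / sum(w)
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i[i < 1] <- 1 - i[i < 1]
      i[i > n] <- 2 * n + 1 - i[i > n]
    }
    i
  }
  d <- dim(x)
  acc <- 0
  for (a in -r:r) for (b in -r:r) for (c in -r:r) {
    acc <- acc + w[a + r + 1] * w[b + r + 1] * w[c + r + 1] *
      x[refl(at[1] + a, d[1]), refl(at[2] + b, d[2]), refl(at[3] + c, d[3])]
  }
  acc
}

# brute-force 6-connected boundary detector (loop oracle)
boundary_oracle <- function(labs) {
  d <- dim(labs)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v <- labs[i, j, k]
    nb <- c(if (i > 1) labs[i - 1, j, k], if (i < d[1]) labs[i + 1, j, k],
            if (j > 1) labs[i, j - 1, k], if (j < d[2]) labs[i, j + 1, k],
            if (k > 1) labs[i, j, k - 1], if (k < d[3]) labs[i, j, k + 1])
    out[i, j, k] <- any(nb != v)
  }
  out
}

# small cohort with volumes, shared across pipeline tests
small_cohort <- function(n = c(YC = 4, Abeta_negative = 3, ADCI = 6),
                         noise_sd = 0.02, flip = 0.5, seed = 11L) {
  make_cohort(cohort_spec(n_per_group = n, seed = seed),
              phantom_spec(noise_sd = noise_sd, seed = seed),
              parcellation_perturbation(1, flip, seed = seed))
}
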