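# Independent brute-force oracles and random-instance generators used
# across the suite.

# Exhaustive triple-loop decomposition of an MMP-kernel model: loops over
# every support vector and every shared (core, substituent) feature pair,
# splitting each cross-term by hand. Deliberately slow and index-wise.
oracle_decompose_mmp <- function(svs, coefs, x) {
  contrib <- list()
  add <- function(key, v) contrib[[key]] <<- (contrib[[key]] %||% 0) + v
  `%||%` <- function(a, b) if (is.null(a)) b else a
  ksum <- 0
  for (i in seq_along(svs)) {
    sv <- svs[[i]]
    for (dc in x$core) for (ds in x$sub) {
      v <- frag_fc_mmp(sv, coefs[i], x, dc, ds)
      if (v == 0) next
      ksum <- ksum + v
      add(paste0("c", dc), v / 2)
      add(paste0("s", ds), v / 2)
    }
  }
  list(contrib = contrib, kernel_sum = ksum)
}

# Plain-Tanimoto contribution oracle over flat identifier sets.
oracle_fc_tanimoto <- function(sv_sets, coefs, x_set) {
  sapply(x_set, function(d)
    sum(vapply(seq_along(sv_sets), function(i)
      frag_fc_tanimoto(sv_sets[[i]], coefs[i], x_set, d), numeric(1))))
}

# Random abstract MMP fingerprint over small id pools.
random_fp <- function(max_bits = 10L, core_pool = 1:12, sub_pool = 1:12) {
  nc <- sample.int(max_bits, 1)
  ns <- sample.int(max_bits, 1)
  mmpcliff:::new_mmp_fp(core = sample(core_pool, min(nc, length(core_pool))),
                        sub = sample(sub_pool, min(ns, length(sub_pool))))
}

# Small planted-cliff MMP table shared by several tests (built once per run).
fixture_mmps <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cp <- generate_cliff_dataset(cliff_spec(n_series = 3L,
                                              series_size = 4L, seed = 42L))
      cache <<- generate_mmps(cp)
    }
    cache
  }
})
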