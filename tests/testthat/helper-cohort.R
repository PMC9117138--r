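# Shared fixtures: small cohorts built in code, cached per test run.

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(sim_config(n_trios = 120, seed = 42))
    }
    cache
  }
})

# a minimal, fully valid autosomal call row
valid_call <- function(...) {
  base <- data.frame(
    trio_id = "t1", child_id = "c1", chrom = "chr1", pos = 1000L,
    ref = "C", alt = "T", vartype = "SNV",
    gt_child = "0/1", gt_father = "0/0", gt_mother = "0/0",
    rd_child = 30L, rd_father = 30L, rd_mother = 30L,
    altreads_father = 0L, altreads_mother = 0L, altreads_child = 15L,
    vaf_child = 0.5, context96 = "A[C>T]G", tx_strand = NA_character_,
    stringsAsFactors = FALSE
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

# write a BED file (0-based half-open) and return its path
write_bed <- function(df, path = tempfile(fileext = ".bed")) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  path
}
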