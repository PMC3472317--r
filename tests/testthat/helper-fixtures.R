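# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

fx_decoys <- function(n = 100, seed = 1) {
  memo(paste0("decoys", n, "_", seed), make_dummy_db(n, seed = seed))
}

# a tight (narrow-spread) family of five
fx_narrow_family <- function() {
  memo("narrow", {
    fam <- make_family(family_spec("NF", 5, 150, c(88, 95), 0.005, seed = 31))
    setNames(fam, vapply(fam, `[[`, character(1), "seq_id"))
  })
}

# two unrelated clusters of three glued into one "family"
fx_two_cluster_family <- function() {
  memo("twocluster", {
    fa <- make_family(family_spec("CA", 3, 150, c(80, 90), 0.01, seed = 37))
    fb <- make_family(family_spec("CB", 3, 150, c(80, 90), 0.01, seed = 38))
    both <- c(fa, fb)
    setNames(both, vapply(both, `[[`, character(1), "seq_id"))
  })
}

fx_backend <- function(seqs, seed = 1) {
  key <- paste0("be_", paste(sort(names(seqs)), collapse = ","), "_", seed)
  memo(key, search_backend(seqs, fx_decoys(seed = seed), pf_config()))
}

fx_benchmark <- function() memo("benchmark", make_benchmark(seed = 61))

# a small legacy classification for datamodel tests
fx_classification <- function() {
  classification(list(
    pf_group("HTH", list(
      pf_family("Cro & repressor", "HTH", c("1LMB_A", "1ORC_A")),
      pf_family("Homeodomain", "HTH", c("1FJL_A", "1HDD_A", "6PAX_A"),
                representative_ids = "1FJL_A",
                fold_labels = c("1FJL_A" = "helical bundle",
                                "1HDD_A" = "helical bundle",
                                "6PAX_A" = NA)))),
    pf_group("Enzyme", list(
      pf_family("DNA polymerase T7", "Enzyme", "1T7P_A"),
      pf_family("Uracil DNA glycosylase", "Enzyme",
                c("1SSP_A", "1AKZ_A", "2SSP_A", "3SSP_A", "4SSP_A"))))))
}

toy_entry <- function(id = "1ABC", resolution = 2.5, na = "dsDNA",
                      nucleosomal = FALSE, classified = FALSE,
                      taxon = "prokaryote", nchains = 1L, len = 40L) {
  chains <- lapply(seq_len(nchains), function(k)
    seq_record(paste0(id, "_", LETTERS[k]), random_protein(len, k + 7),
               source_taxon = taxon))
  complex_entry(id, resolution, na, nucleosomal, classified, chains)
}
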