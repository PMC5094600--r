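# shared helpers: random sequences and a small cached peptide database

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_protein <- function(n) {
  paste(sample(swingerome:::AA20, n, replace = TRUE), collapse = "")
}

# one small database shared across tests (built once per test run)
.db_cache <- new.env()
small_db <- function() {
  if (is.null(.db_cache$db)) {
    g <- randomGenome(1200, 0.44, seed = 424242, id = "toy")
    .db_cache$db <- buildPeptideDatabase(
      g, analyses = c("del", "swinger_tri"))$database
  }
  .db_cache$db
}
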