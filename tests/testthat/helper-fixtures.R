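# Shared fixture builders: everything is generated in code at test time.

# correlated bivariate normal sample (x, y) with population correlation rho
rbvn <- function(n, rho, mean = 0, sd = 1) {
  z1 <- rnorm(n); z2 <- rnorm(n)
  cbind(x = mean + sd * z1,
        y = mean + sd * (rho * z1 + sqrt(1 - rho^2) * z2))
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# tiny 3-probe x 2-sample expression TSV
tiny_matrix_fixture <- function() {
  write_tsv_fixture(c("probe_id\ts1\ts2",
                      "p1\t1.5\t2.5",
                      "p2\t3\t4.25",
                      "p3\t-0.5\t0"))
}

# minimal KGML document: two single-gene entries, one two-gene entry, a
# group over entries 1 and 2, and configurable relations
tiny_kgml <- function(relations = '<relation entry1="1" entry2="2" type="PPrel"/>') {
  paste0('<?xml version="1.0"?>\n',
         '<pathway name="path:hsa00001" org="hsa" title="tiny pathway">\n',
         '<entry id="1" name="hsa:10" type="gene"/>\n',
         '<entry id="2" name="hsa:20" type="gene"/>\n',
         '<entry id="3" name="hsa:30 hsa:31" type="gene"/>\n',
         '<entry id="4" name="undefined" type="group">',
         '<component id="1"/><component id="2"/></entry>\n',
         paste(relations, collapse = "\n"),
         "\n</pathway>")
}

# synthetic dataset with n_diff differential pairs (rho_ref vs rho_test)
# among n_null pairs sharing rho 0 in both conditions
planted_spec <- function(n_diff, n_null, n_per_cond = 150L, rho_ref = 0.8,
                         rho_test = 0, seed = 1L, ...) {
  n <- n_diff + n_null
  synthetic_spec(
    pair_specs = data.frame(
      gene_a = sprintf("hsa:a%04d", seq_len(n)),
      gene_b = sprintf("hsa:b%04d", seq_len(n)),
      rho_ref = c(rep(rho_ref, n_diff), rep(0, n_null)),
      rho_test = c(rep(rho_test, n_diff), rep(0, n_null)),
      stringsAsFactors = FALSE),
    n_samples = c(nonrelapse = n_per_cond, relapse = n_per_cond),
    seed = seed, ...)
}
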