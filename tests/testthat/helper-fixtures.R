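# Shared fixture builders: everything is generated in code at test time.

# write a FASTA file from a named vector, return its path
tmp_fasta <- function(seqs, ...) {
  path <- withr::local_tempfile(fileext = ".fasta", .local_envir = parent.frame())
  writeLines(unlist(lapply(names(seqs), function(id) c(paste0(">", id), seqs[[id]]))),
             path)
  path
}

# write a TSV from a data frame, return its path
tmp_tsv <- function(df, ...) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# write raw lines, return path
tmp_lines <- function(lines, fileext = ".txt") {
  path <- withr::local_tempfile(fileext = fileext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# random DNA string of length n under the current RNG state
rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# copy of `seq` with exactly `k` substitutions
mutate_seq <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  paste(chars, collapse = "")
}

# a small separable community reused across classifier tests
small_params <- function(seed = 7, ...) {
  generator_params(n_indigenous = 6, n_contaminant = 4, asv_length = 120,
                   n_samples = 4, read_depth = 2000, seed = seed, ...)
}
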