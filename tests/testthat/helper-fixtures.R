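# shared fixture helpers: small synthetic projects built in code

local_project <- function(..., env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  generate_project(fixture_spec(...), dir)
}

# a scaled-down default project: 6 proteins, 2 peptides each, 4 spectra per
# peptide, 4 channels, two replicates
small_project <- function(env = parent.frame(), ...) {
  local_project(n_proteins = 6, peptides_per_protein = 2,
                spectra_per_peptide = 4, n_channels = 4, seed = 11,
                env = env, ...)
}

run_project <- function(fx, config = NULL, ...) {
  if (is.null(config)) config <- load_reporting_config(fx$paths$config)
  run_maxreport(fx$dir, config, fx$paths$fasta, fx$paths$rule,
                correction_matrix = fx$paths$correction_matrix, ...)
}

n_log <- function(level) nrow(mr_log_entries(level))

write_lines_tmp <- function(lines, env = parent.frame()) {
  f <- withr::local_tempfile(.local_envir = env)
  writeLines(lines, f)
  f
}
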