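# internal helpers shared across modules

# nA carried by one elementary charge per picosecond:
# 1.602176634e-19 C / 1e-12 s = 1.602176634e-7 A
.E_PER_PS_NA <- 160.2176634

.species_levels <- c("WATER", "ION_K", "ION_CL", "PEPTIDE", "PORE",
                     "LIPID", "OTHER")

.assert_scalar_num <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

.check_species <- function(species) {
  species <- as.character(species)
  bad <- setdiff(species, .species_levels)
  if (length(bad))
    stop("unknown species: ", paste(bad, collapse = ", "),
         " (valid: ", paste(.species_levels, collapse = ", "), ")",
         call. = FALSE)
  species
}

# run code with a private, restorable RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
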