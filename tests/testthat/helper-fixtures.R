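# Shared helpers: small parameter sets and hand-built datasets.

# Default calibration with selective overrides.
params_with <- function(...) {
  p <- calibration_default()
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}

# Calibration with the hierarchy collapsed: no inter-individual variance
# and (numerically) no dropout, so cells are i.i.d. negative binomial.
iid_params <- function() {
  params_with(f1_intercept = 0, f1_slope = 0,
              dropout_shape = 1e-3, dropout_rate = 1e6)
}

# Build a cell_obs object directly from raw counts and labels.
make_cells <- function(raw, individual, group) {
  cell_observations(list(values = raw,
                         individual_ids = as.character(individual),
                         group_labels = as.integer(group)))
}

# Build a multigene_matrix from a plain matrix and individual labels.
make_mgm <- function(counts, individual, group = NULL, cell_type = NULL) {
  md <- data.frame(cell_id = paste0("c", seq_len(ncol(counts))),
                   individual_id = as.character(individual),
                   stringsAsFactors = FALSE)
  if (!is.null(group)) md$group <- group
  if (!is.null(cell_type)) md$cell_type <- cell_type
  multigene_matrix(counts, md)
}
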