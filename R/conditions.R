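# Classed conditions so callers (and the CLI) can map failures to exit codes.

rds_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "rds_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

rds_spec_error <- function(message) rds_abort(message, "rds_spec_error")
rds_io_error <- function(message) rds_abort(message, "rds_io_error")
rds_format_error <- function(message) rds_abort(message, "rds_format_error")
rds_shape_error <- function(message) rds_abort(message, "rds_shape_error")
rds_numeric_error <- function(message) rds_abort(message, "rds_numeric_error")
rds_label_error <- function(message) rds_abort(message, "rds_label_error")
rds_metric_error <- function(message) rds_abort(message, "rds_metric_error")
rds_divergence_error <- function(message) rds_abort(message, "rds_divergence_error")

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never perturbs user RNG
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
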