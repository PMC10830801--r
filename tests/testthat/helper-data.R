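# Tiny fixtures built in code.

make_table <- function(intensities, rt = NULL, mz = NULL, groups) {
  n <- nrow(intensities)
  feature_table(
    intensities,
    feature_meta = tibble::tibble(
      feature_id = sprintf("F%03d", seq_len(n)),
      mz = mz %||% seq(100, 200, length.out = n),
      rt = rt %||% seq(3, 18, length.out = n)
    ),
    sample_meta = tibble::tibble(
      sample_id = sprintf("S%02d", seq_along(groups)),
      group = groups
    )
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
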