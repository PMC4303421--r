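# ---------------------------------------------------------------------------
# Registration of the built-in operators with the framework.  Each wraps a
# plain function from image_ops.R / lbp.R / signal_ops.R behind a
# descriptor + validator, so stacks can be processed by name.
# ---------------------------------------------------------------------------

grey_source_validator <- function(sources, params) {
  s <- sources[[1]]
  if (!inherits(s, "image_item") || !is_grey(s))
    "requires a single-band grey value image at position 0"
  else character(0)
}

odd_check <- function(v) v %% 2 == 1

register_builtin_ops <- function() {
  if (!is.null(.op_registry[["op.invert"]])) return(invisible(FALSE))

  register_operator(
    operator_descriptor("op.invert", "image", 1L, list(), "image"),
    function(sources, params)
      multi_result(images = list(invert(sources[[1]]))),
    validator = grey_source_validator)

  register_operator(
    operator_descriptor("op.histnorm", "image", 1L, list(), "image"),
    function(sources, params)
      multi_result(images = list(normalize_histogram(sources[[1]]))),
    validator = grey_source_validator)

  register_operator(
    operator_descriptor("op.meangrey", "image", 1L, list(),
                        output_kinds = "table"),
    function(sources, params)
      multi_result(tables = list(table_item(
        "mean_grey", data.frame(mean_grey = mean_grey(sources[[1]])),
        name = "mean grey value"))),
    validator = grey_source_validator)

  register_operator(
    operator_descriptor("op.histstats", "image", 1L, list(),
                        output_kinds = "table"),
    function(sources, params) {
      st <- histogram_statistics(sources[[1]])
      multi_result(tables = list(table_item(
        names(st), as.data.frame(st), name = "histogram statistics")))
    },
    validator = grey_source_validator)

  register_operator(
    operator_descriptor("op.absdiff", "image", 2L, list(), "image"),
    function(sources, params)
      multi_result(images = list(abs_difference(sources[[1]], sources[[2]]))),
    validator = function(sources, params) {
      msgs <- character(0)
      for (i in 1:2)
        if (!inherits(sources[[i]], "image_item") || !is_grey(sources[[i]]))
          msgs <- c(msgs, sprintf(
            "requires a single-band grey value image at position %d", i - 1))
      if (length(msgs) == 0L &&
          !identical(dim(sources[[1]]$pixels), dim(sources[[2]]$pixels)))
        msgs <- sprintf("shape mismatch: %dx%d vs %dx%d",
                        nrow(sources[[1]]$pixels), ncol(sources[[1]]$pixels),
                        nrow(sources[[2]]$pixels), ncol(sources[[2]]$pixels))
      msgs
    })

  register_operator(
    operator_descriptor("op.smooth", "image", 1L, list(
      parameter_spec("Kernel size k", "INT", 3L, min = 3L, max = 101L,
                     check = odd_check,
                     describe = "Validk={2i+1 in Z+ | i in N+, i<=50}"),
      parameter_spec("Sigma", "FLOAT", 0.5, min = 1e-8,
                     describe = "FLOAT > 0")),
      "image"),
    function(sources, params)
      multi_result(images = list(gaussian_smooth(
        sources[[1]], params[["Kernel size k"]], params[["Sigma"]]))),
    validator = grey_source_validator)

  register_operator(
    operator_descriptor("op.dog", "image", 1L, list(
      parameter_spec("Sigma 1", "FLOAT", 1.0, min = 1e-8,
                     describe = "FLOAT > 0"),
      parameter_spec("Sigma 2", "FLOAT", 2.0, min = 1e-8,
                     describe = "FLOAT > Sigma 1")),
      "image"),
    function(sources, params)
      multi_result(images = list(dog_edge(
        sources[[1]], params[["Sigma 1"]], params[["Sigma 2"]]))),
    validator = function(sources, params) {
      msgs <- grey_source_validator(sources, params)
      if (params[["Sigma 2"]] <= params[["Sigma 1"]])
        msgs <- c(msgs, "Sigma 2 must exceed Sigma 1")
      msgs
    })

  register_operator(
    operator_descriptor("op.regiongrow", "image", 1L, list(
      parameter_spec("Seed row", "INT", 0L, min = 0L),
      parameter_spec("Seed col", "INT", 0L, min = 0L),
      parameter_spec("Tolerance", "FLOAT", 0, min = 0)),
      output_kinds = c("image", "table")),
    function(sources, params) {
      rg <- region_grow(sources[[1]],
                        c(params[["Seed row"]], params[["Seed col"]]),
                        params[["Tolerance"]])
      L <- sample_model_max(sources[[1]]$sample_model)
      mask_img <- image_item(matrix(as.numeric(rg$mask) * L,
                                    nrow = nrow(rg$mask)),
                             sources[[1]]$sample_model, name = "region mask")
      multi_result(images = list(mask_img),
                   tables = list(table_item(
                     "area", data.frame(area = rg$area),
                     name = "region area")))
    },
    validator = function(sources, params) {
      msgs <- grey_source_validator(sources, params)
      if (length(msgs) == 0L) {
        d <- dim(sources[[1]]$pixels)
        if (params[["Seed row"]] >= d[1] || params[["Seed col"]] >= d[2])
          msgs <- sprintf("seed (%d, %d) out of bounds for a %dx%d image",
                          params[["Seed row"]], params[["Seed col"]],
                          d[1], d[2])
      }
      msgs
    })

  # LBP with the published parameter names and valid ranges
  register_operator(
    operator_descriptor("op.lbp", "image", 1L, list(
      parameter_spec("Neighbours P", "INT", 8L, min = 1L, max = 32L,
                     describe = "ValidP={P in Z+ | 1<=P<=32}"),
      parameter_spec("Radius R", "FLOAT", 1.0, min = 1.0,
                     describe = "ValidR={R in R+ | R>=1.0}"),
      parameter_spec("Smooth (Gaussian)", "BOOLEAN", FALSE,
                     describe = "{true | false}"),
      parameter_spec("Kernel size k", "INT", 3L, min = 3L, max = 101L,
                     check = odd_check,
                     describe = "Validk={2i+1 in Z+ | i in N+, i<=50}"),
      parameter_spec("Cells C", "INT", 1L, min = 1L,
                     describe = "ValidC={C in N+ | 1<=C<=max{M,N}}"),
      parameter_spec("Rotation invariant", "BOOLEAN", TRUE,
                     describe = "{true | false}")),
      output_kinds = c("image", "signal", "table")),
    function(sources, params) {
      res <- lbp_transform(sources[[1]],
        lbp_params(P = params[["Neighbours P"]], R = params[["Radius R"]],
                   smooth = params[["Smooth (Gaussian)"]],
                   k = params[["Kernel size k"]], C = params[["Cells C"]]),
        rotation_invariance = params[["Rotation invariant"]])
      hist_signals <- lapply(seq_along(res$cell_histograms), function(i)
        signal_item(as.numeric(res$cell_histograms[[i]]),
                    name = sprintf("lbp histogram cell %d", i)))
      multi_result(images = list(res$code_image), signals = hist_signals,
                   tables = res$code_tables,
                   custom = list(res$descriptor))
    },
    validator = function(sources, params) {
      msgs <- grey_source_validator(sources, params)
      if (length(msgs) == 0L) {
        d <- dim(sources[[1]]$pixels)
        if (params[["Cells C"]] > max(d))
          msgs <- sprintf(
            "Cells C = %d outside valid range 1 <= C <= max{M,N} = %d",
            params[["Cells C"]], max(d))
      }
      msgs
    })

  register_operator(
    operator_descriptor("op.medfilt1d", "signal", 1L, list(
      parameter_spec("Window", "INT", 5L, min = 1L, check = odd_check,
                     describe = "odd INT >= 1")),
      output_kinds = "signal"),
    function(sources, params)
      multi_result(signals = list(median_filter(sources[[1]],
                                                params[["Window"]]))))

  register_operator(
    operator_descriptor("op.extrema", "signal", 1L, list(
      parameter_spec("Min prominence", "FLOAT", 0, min = 0)),
      output_kinds = "table"),
    function(sources, params) {
      ex <- find_extrema(sources[[1]], params[["Min prominence"]])
      multi_result(tables = list(table_item(
        c("index", "type"),
        data.frame(index = c(ex$maxima, ex$minima),
                   type = rep(c("max", "min"),
                              c(length(ex$maxima), length(ex$minima)))),
        name = "extrema")))
    })

  invisible(TRUE)
}
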