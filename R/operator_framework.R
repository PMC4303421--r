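# ---------------------------------------------------------------------------
# Operator framework: descriptors, parameter specs, a process-wide registry,
# validation, execution (single / serial stack / parallel stack), templates.
# ---------------------------------------------------------------------------

.op_registry <- new.env(parent = emptyenv())

#' Declare an operator parameter
#'
#' @param name Parameter name (as used in parameter blocks).
#' @param ptype `"INT"`, `"FLOAT"` or `"BOOLEAN"`.
#' @param default Default value; must satisfy the valid range.
#' @param min,max Optional inclusive bounds (INT/FLOAT).
#' @param check Optional extra predicate `function(value) TRUE/FALSE`.
#' @param describe Human-readable description of the valid range, quoted in
#'   validation messages.
#' @return A `parameter_spec` object.
#' @export
parameter_spec <- function(name, ptype = c("INT", "FLOAT", "BOOLEAN"),
                           default, min = NULL, max = NULL, check = NULL,
                           describe = NULL) {
  ptype <- match.arg(ptype)
  spec <- structure(
    list(name = name, ptype = ptype, default = default, min = min, max = max,
         check = check,
         describe = describe %||% default_range_text(ptype, min, max)),
    class = "parameter_spec")
  if (!param_ok(spec, default))
    stop_parameter(sprintf("default %s for parameter '%s' violates %s",
                           format(default), name, spec$describe))
  spec
}

default_range_text <- function(ptype, min, max) {
  if (ptype == "BOOLEAN") return("{true | false}")
  lo <- if (is.null(min)) "-Inf" else format(min)
  hi <- if (is.null(max)) "Inf" else format(max)
  sprintf("%s in [%s, %s]", ptype, lo, hi)
}

param_ok <- function(spec, value) {
  if (length(value) != 1L || is.na(value)) return(FALSE)
  ok <- switch(spec$ptype,
    BOOLEAN = is.logical(value),
    INT = is.numeric(value) && value == floor(value),
    FLOAT = is.numeric(value))
  if (!ok) return(FALSE)
  if (!is.null(spec$min) && value < spec$min) return(FALSE)
  if (!is.null(spec$max) && value > spec$max) return(FALSE)
  if (!is.null(spec$check) && !isTRUE(spec$check(value))) return(FALSE)
  TRUE
}

#' Describe an operator
#'
#' The descriptor is an operator's public identity: its unique
#' (protocol-like) name, whether it processes images or signals, how many
#' sources it takes, its parameter specs with valid ranges, and which result
#' kinds it can produce.
#'
#' @param unique_name Non-empty name, unique within the registry.
#' @param op_type `"image"` or `"signal"`.
#' @param n_sources Number of sources (>= 1).
#' @param params List of [parameter_spec()] objects.
#' @param output_kinds Subset of `c("image", "signal", "table", "custom")`.
#' @return An `operator_descriptor` object.
#' @export
operator_descriptor <- function(unique_name, op_type = c("image", "signal"),
                                n_sources = 1L, params = list(),
                                output_kinds = "image") {
  op_type <- match.arg(op_type)
  if (!nzchar(unique_name))
    stop_parameter("operator name must be non-empty")
  if (n_sources < 1L)
    stop_parameter("n_sources must be >= 1")
  bad <- setdiff(output_kinds, c("image", "signal", "table", "custom"))
  if (length(bad) > 0L)
    stop_parameter(sprintf("unknown output kind '%s'", bad[1]))
  names(params) <- vapply(params, `[[`, "", "name")
  structure(
    list(unique_name = unique_name, op_type = op_type,
         n_sources = as.integer(n_sources), params = params,
         output_kinds = output_kinds),
    class = "operator_descriptor")
}

#' @export
print.operator_descriptor <- function(x, ...) {
  cat(sprintf("Operator %s (%s, %d source%s)\n", x$unique_name, x$op_type,
              x$n_sources, if (x$n_sources > 1) "s" else ""))
  cat(sprintf("  outputs: %s\n", paste(x$output_kinds, collapse = ", ")))
  for (p in x$params)
    cat(sprintf("  param %-12s %-8s default=%-6s valid: %s\n", p$name,
                p$ptype, format(p$default), p$describe))
  invisible(x)
}

#' Build a complete parameter block for an operator
#'
#' Fills unspecified parameters with their descriptor defaults.
#'
#' @param descriptor An `operator_descriptor` (or registered operator name).
#' @param ... Named parameter values overriding the defaults.
#' @return Named list with one entry per parameter spec.
#' @export
parameter_block <- function(descriptor, ...) {
  if (is.character(descriptor)) descriptor <- get_operator(descriptor)$descriptor
  given <- list(...)
  if (length(given) == 1L && is.list(given[[1]]) && is.null(names(given)[1]))
    given <- given[[1]]
  unknown <- setdiff(names(given), names(descriptor$params))
  if (length(unknown) > 0L)
    stop_parameter(sprintf("unknown parameter '%s' for operator %s",
                           unknown[1], descriptor$unique_name))
  block <- lapply(descriptor$params, `[[`, "default")
  block[names(given)] <- given
  block
}

#' Register an operator
#'
#' @param descriptor An [operator_descriptor()].
#' @param algorithm `function(sources, params)` returning a [multi_result()];
#'   `sources` is a list of payload items, `params` a complete block.
#' @param validator Optional custom checker `function(sources, params)`
#'   returning a character vector of failure messages (empty when fine).
#' @return The operator name, invisibly.
#' @export
register_operator <- function(descriptor, algorithm, validator = NULL) {
  name <- descriptor$unique_name
  if (!is.null(.op_registry[[name]]))
    stop_stackops("stackops_registration_error",
      sprintf("operator '%s' is already registered", name))
  .op_registry[[name]] <- list(descriptor = descriptor, algorithm = algorithm,
                               validator = validator)
  invisible(name)
}

#' Look up a registered operator
#' @param name Operator name.
#' @return List with `descriptor`, `algorithm`, `validator`.
#' @export
get_operator <- function(name) {
  entry <- .op_registry[[name]]
  if (is.null(entry))
    stop_not_found(sprintf("operator '%s' is not registered", name))
  entry
}

#' Names of all registered operators
#' @return Character vector.
#' @export
list_operators <- function() sort(ls(.op_registry))

# Used by tests; not part of normal operation.
unregister_operator <- function(name) {
  if (exists(name, envir = .op_registry)) rm(list = name, envir = .op_registry)
  invisible(NULL)
}

#' Bundle an operator invocation
#'
#' A work package is one executable unit: the operator name, its ordered
#' sources and a parameter block.
#'
#' @param operator_name Registered operator name.
#' @param sources List of data items (or bare payload items).
#' @param params Parameter block (see [parameter_block()]); missing entries
#'   are filled with defaults at validation/execution time.
#' @return A `work_package` object.
#' @export
work_package <- function(operator_name, sources, params = list()) {
  if (inherits(sources, c("image_item", "signal_item", "table_item",
                          "data_item")))
    sources <- list(sources)
  structure(list(operator_name = operator_name, sources = sources,
                 params = params),
            class = "work_package")
}

#' Heterogeneous operator result
#'
#' Operators return zero or more images, signals, tables and opaque custom
#' objects.
#'
#' @param images,signals,tables,custom Lists of result components.
#' @return A `multi_result` object.
#' @export
multi_result <- function(images = list(), signals = list(), tables = list(),
                         custom = list()) {
  structure(list(images = images, signals = signals, tables = tables,
                 custom = custom),
            class = "multi_result")
}

#' @export
print.multi_result <- function(x, ...) {
  cat(sprintf("<multi_result: %d image(s), %d signal(s), %d table(s), %d custom>\n",
              length(x$images), length(x$signals), length(x$tables),
              length(x$custom)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Validation
# ---------------------------------------------------------------------------

#' Validate a work package
#'
#' Checks, in order: source count against the descriptor's arity, source
#' kinds against the operator type, every parameter against its valid range,
#' then the operator's custom validator (e.g. a colour-model check).  All
#' failures are collected, not just the first.
#'
#' @param work A [work_package()].
#' @return A `validation_report` with fields `ok` and `messages`
#'   (`ok` is `TRUE` iff `messages` is empty).
#' @export
validate <- function(work) {
  entry <- get_operator(work$operator_name)
  desc <- entry$descriptor
  msgs <- character(0)

  if (length(work$sources) != desc$n_sources)
    msgs <- c(msgs, sprintf("operator %s expects %d source(s), got %d",
                            desc$unique_name, desc$n_sources,
                            length(work$sources)))

  expected_kind <- desc$op_type
  for (i in seq_along(work$sources)) {
    s <- work$sources[[i]]
    kind <- if (inherits(s, "data_item")) s$kind
            else if (inherits(s, "image_item")) "image"
            else if (inherits(s, "signal_item")) "signal"
            else if (inherits(s, "table_item")) "table"
            else "unknown"
    if (kind != expected_kind)
      msgs <- c(msgs, sprintf("source %d has kind '%s', operator %s expects '%s'",
                              i, kind, desc$unique_name, expected_kind))
  }

  block <- tryCatch(parameter_block(desc, work$params),
                    stackops_parameter_error = function(e) e)
  if (inherits(block, "condition")) {
    msgs <- c(msgs, conditionMessage(block))
    block <- lapply(desc$params, `[[`, "default")
  }
  for (p in desc$params) {
    v <- block[[p$name]]
    if (!param_ok(p, v))
      msgs <- c(msgs, sprintf(
        "parameter '%s' = %s is outside its valid range (%s)", p$name,
        format(v), p$describe))
  }

  if (length(msgs) == 0L && !is.null(entry$validator)) {
    payloads <- lapply(work$sources, item_payload)
    custom <- tryCatch(entry$validator(payloads, block),
                       error = function(e) conditionMessage(e))
    msgs <- c(msgs, custom)
  }

  structure(list(ok = length(msgs) == 0L, messages = msgs),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) cat("validation: ok\n")
  else cat("validation failed:\n", paste0("  - ", x$messages, collapse = "\n"),
           "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Execution
# ---------------------------------------------------------------------------

#' Execute a work package
#'
#' Virtual sources are materialized on demand; when the session is in
#' virtual mode ([virtual_mode()]), result items are re-virtualized before
#' returning.  Validation may be bypassed when a processing chain clearly
#' defines the operator's inputs.
#'
#' @param work A [work_package()].
#' @param bypass_validation Skip [validate()] (default `FALSE`).
#' @return A [multi_result()].
#' @export
execute <- function(work, bypass_validation = FALSE) {
  entry <- get_operator(work$operator_name)
  if (!bypass_validation) {
    report <- validate(work)
    if (!report$ok)
      stop_validation(sprintf("validation of operator %s failed:\n%s",
                              work$operator_name,
                              paste0("  - ", report$messages, collapse = "\n")),
                      report = report)
  }
  payloads <- lapply(work$sources, item_payload)
  block <- parameter_block(entry$descriptor, work$params)
  result <- tryCatch(entry$algorithm(payloads, block), error = function(e) {
    if (inherits(e, "stackops_error")) stop(e)
    stop_execution(sprintf("operator %s failed: %s", work$operator_name,
                           conditionMessage(e)))
  })
  if (!inherits(result, "multi_result"))
    stop_execution(sprintf("operator %s returned a non-multi_result",
                           work$operator_name))
  if (virtual_mode_enabled()) {
    result$images <- lapply(result$images, virtualize)
    result$signals <- lapply(result$signals, virtualize)
    result$tables <- lapply(result$tables, virtualize)
  }
  result
}

# One stack element supplies the operator's sources: a single item for
# ordinary single-source operators, or a plain list of k items for a
# k-source operator (e.g. image pairs for a difference operator).
stack_sources <- function(item) {
  if (is.list(item) && !inherits(item, c("image_item", "signal_item",
                                         "table_item", "data_item")))
    item
  else list(item)
}

#' Process a stack serially (first-in first-out)
#'
#' Items may be heterogeneous in size and sample model; homogeneity is the
#' business of each operator's validator, not of the stack.  Item `i`'s
#' result depends only on item `i` and the shared parameters, and results
#' keep the input order.  An element of `stack` is a single item (or
#' `data_item`), or a plain list of items for multi-source operators.
#'
#' @param stack List of data items (or payload items).
#' @param operator_name Registered single-source operator.
#' @param params Shared parameter block.
#' @param on_error `"fail"` (default) aborts at the first failing item with
#'   its index; `"skip"` collects errors and drops the item's slot to `NULL`.
#' @return List of [multi_result()], same order/length as `stack`
#'   (failed slots `NULL` under `"skip"`).
#' @export
execute_serial <- function(stack, operator_name, params = list(),
                           on_error = c("fail", "skip")) {
  on_error <- match.arg(on_error)
  get_operator(operator_name)  # fail early on unknown operator
  out <- vector("list", length(stack))
  for (i in seq_along(stack)) {
    res <- tryCatch(
      execute(work_package(operator_name, stack_sources(stack[[i]]), params)),
      stackops_error = function(e) e)
    if (inherits(res, "condition")) {
      if (on_error == "fail")
        stop_stackops(class(res)[1],
          sprintf("stack item %d: %s", i, conditionMessage(res)))
      out[i] <- list(NULL)
    } else out[[i]] <- res
  }
  out
}

#' Process a stack in parallel
#'
#' Contract: the output is element-wise identical to [execute_serial()] on
#' the same inputs, with the input order restored regardless of completion
#' order.  The worker implementation is unspecified.
#'
#' @inheritParams execute_serial
#' @param workers Number of workers (>= 1); 1 falls back to serial.
#' @return List of [multi_result()] in input order.
#' @export
execute_parallel <- function(stack, operator_name, params = list(),
                             workers = 2L, on_error = c("fail", "skip")) {
  on_error <- match.arg(on_error)
  if (!is.numeric(workers) || workers < 1L)
    stop_parameter("workers must be a positive integer")
  get_operator(operator_name)
  if (workers == 1L || length(stack) <= 1L ||
      .Platform$OS.type == "windows")
    return(execute_serial(stack, operator_name, params, on_error))
  run_one <- function(item) tryCatch(
    execute(work_package(operator_name, stack_sources(item), params)),
    stackops_error = function(e) e)
  out <- parallel::mclapply(stack, run_one, mc.cores = as.integer(workers),
                            mc.preschedule = TRUE)
  for (i in seq_along(out)) {
    res <- out[[i]]
    if (inherits(res, "condition") || inherits(res, "try-error")) {
      if (on_error == "fail")
        stop_stackops(if (inherits(res, "condition")) class(res)[1]
                      else "stackops_execution_error",
          sprintf("stack item %d: %s", i,
                  if (inherits(res, "condition")) conditionMessage(res)
                  else as.character(res)))
      out[i] <- list(NULL)
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Persistent parameter templates (plain-text key/value files).
# ---------------------------------------------------------------------------

#' Directory holding parameter templates
#' @param dir Optional override; remembered for the session.
#' @return The template directory path.
#' @export
template_dir <- function(dir = NULL) {
  if (!is.null(dir)) .stackops_state$template_dir <- dir
  .stackops_state$template_dir %||%
    tools::R_user_dir("stackops", which = "config")
}

template_path <- function(name, dir) file.path(dir, paste0(name, ".template"))

#' Save a validated parameter block as a persistent template
#'
#' Templates are plain-text key/value files (one per template, filename =
#' template name) and survive process restarts.
#'
#' @param name Template name.
#' @param operator_name Operator the block belongs to.
#' @param params Parameter block; validated against the descriptor.
#' @param dir Template directory (defaults to [template_dir()]).
#' @return Path of the stored template, invisibly.
#' @export
save_template <- function(name, operator_name, params, dir = template_dir()) {
  desc <- get_operator(operator_name)$descriptor
  block <- parameter_block(desc, params)
  for (p in desc$params)
    if (!param_ok(p, block[[p$name]]))
      stop_validation(sprintf(
        "parameter '%s' = %s is outside its valid range (%s)", p$name,
        format(block[[p$name]]), p$describe))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lines <- c(paste0("operator=", operator_name),
             vapply(names(block), function(k) {
               v <- block[[k]]
               tag <- if (is.logical(v)) "B" else if (v == floor(v)) "I" else "F"
               sprintf("%s=%s:%s", k, tag, format(v, digits = 17))
             }, ""))
  writeLines(lines, template_path(name, dir))
  invisible(template_path(name, dir))
}

#' Load a stored parameter template
#'
#' @param name Template name.
#' @param dir Template directory.
#' @return List with `operator` and `params` (the parameter block).
#' @export
load_template <- function(name, dir = template_dir()) {
  path <- template_path(name, dir)
  if (!file.exists(path))
    stop_not_found(sprintf("template '%s' not found under '%s'", name, dir))
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  op <- NULL
  params <- list()
  for (p in kv) {
    if (p[1] == "operator") { op <- p[2]; next }
    tv <- strsplit(p[2], ":", fixed = TRUE)[[1]]
    v <- switch(tv[1],
                B = as.logical(tv[2]),
                I = as.integer(tv[2]),
                F = as.numeric(tv[2]),
                as.numeric(tv[2]))
    params[[p[1]]] <- v
  }
  list(operator = op, params = params)
}
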