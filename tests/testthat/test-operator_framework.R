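# The built-in operators are registered at load time; custom operators
# registered by tests are removed again via the internal helper.

local_operator <- function(name, descriptor, algorithm, validator = NULL,
                           env = parent.frame()) {
  register_operator(descriptor, algorithm, validator)
  withr::defer(stackops:::unregister_operator(name), envir = env)
}

test_that("registry resolves operators by unique name and rejects duplicates", {
  d <- operator_descriptor("op.test.id", "image", 1L, list(), "image")
  local_operator("op.test.id", d,
                 function(sources, params)
                   multi_result(images = list(sources[[1]])))
  expect_identical(get_operator("op.test.id")$descriptor$unique_name,
                   "op.test.id")
  expect_error(register_operator(d, function(s, p) multi_result()),
               class = "stackops_registration_error")
  expect_error(get_operator("op.nope"), class = "stackops_not_found_error")
  expect_true("op.lbp" %in% list_operators())
})

test_that("validation reports every failure, in the documented order", {
  img <- constant_image(10)
  ok <- validate(work_package("op.lbp", list(img),
                              list("Neighbours P" = 8L, "Radius R" = 1.0)))
  expect_true(ok$ok)
  expect_length(ok$messages, 0L)

  bad <- validate(work_package("op.lbp", list(img),
                               list("Neighbours P" = 33L)))
  expect_false(bad$ok)
  expect_match(bad$messages, "Neighbours P", all = FALSE)
  expect_match(bad$messages, "1<=P<=32", all = FALSE)

  # wrong arity and wrong source kind are both reported
  r <- validate(work_package("op.absdiff", list(img)))
  expect_false(r$ok)
  expect_match(r$messages, "expects 2 source", all = FALSE)

  rgb <- image_item(array(5, c(2, 2, 3)), "rgb24")
  r <- validate(work_package("op.lbp", list(rgb)))
  expect_false(r$ok)
  expect_match(r$messages, "single-band grey value image at position 0",
               all = FALSE)
})

test_that("parameter boundary probing matches the declared valid ranges", {
  img <- constant_image(10)
  probe <- function(params) validate(work_package("op.lbp", list(img),
                                                  params))$ok
  expect_true(probe(list("Neighbours P" = 1L)))
  expect_true(probe(list("Neighbours P" = 32L)))
  expect_false(probe(list("Neighbours P" = 0L)))
  expect_false(probe(list("Neighbours P" = 33L)))
  expect_true(probe(list("Radius R" = 1.0)))
  expect_false(probe(list("Radius R" = 0.99)))
  expect_true(probe(list("Kernel size k" = 3L)))
  expect_true(probe(list("Kernel size k" = 101L)))
  expect_false(probe(list("Kernel size k" = 4L)))
  expect_false(probe(list("Kernel size k" = 103L)))
  expect_true(probe(list("Cells C" = 1L)))
  expect_false(probe(list("Cells C" = 0L)))
})

test_that("execute validates unless bypassed, and tags algorithm failures", {
  img <- constant_image(50)
  expect_error(
    execute(work_package("op.lbp", list(img), list("Neighbours P" = 40L))),
    class = "stackops_validation_error")
  # bypass skips the descriptor checks and fails inside the algorithm
  expect_error(
    execute(work_package("op.lbp", list(img), list("Neighbours P" = 40L)),
            bypass_validation = TRUE),
    class = "stackops_validation_error")
  res <- execute(work_package("op.invert", list(img)))
  expect_equal(res$images[[1]]$pixels, matrix(205, 8, 8))
})

test_that("smoothing a constant image through the framework is the identity", {
  img <- constant_image(123, 6, 9)
  res <- execute(work_package("op.smooth", list(img),
                              list("Kernel size k" = 5L, "Sigma" = 1.0)))
  expect_equal(res$images[[1]]$pixels, img$pixels)
})

test_that("serial stacks preserve order, handle heterogeneous sizes, fail fast", {
  stack <- list(constant_image(10, 4, 4), constant_image(200, 7, 5),
                constant_image(99, 3, 12))
  res <- execute_serial(stack, "op.histnorm")
  expect_length(res, 3L)
  for (i in 1:3)  # constant images come back unchanged, sizes preserved
    expect_identical(dim(res[[i]]$images[[1]]$pixels), dim(stack[[i]]$pixels))

  expect_identical(execute_serial(list(), "op.invert"), list())

  a <- constant_image(3); b <- constant_image(4)
  res <- execute_serial(list(a, b), "op.invert")
  expect_equal(res[[1]]$images[[1]]$pixels[1, 1], 252)
  expect_equal(res[[2]]$images[[1]]$pixels[1, 1], 251)

  mixed <- list(constant_image(1), image_item(array(1, c(2, 2, 3)), "rgb24"))
  err <- tryCatch(execute_serial(mixed, "op.invert"), error = function(e) e)
  expect_s3_class(err, "stackops_validation_error")
  expect_match(conditionMessage(err), "stack item 2")
  skipped <- execute_serial(mixed, "op.invert", on_error = "skip")
  expect_false(is.null(skipped[[1]]))
  expect_null(skipped[[2]])
})

test_that("parallel execution equals serial element-wise for every operator", {
  set.seed(42)
  sizes <- cbind(sample(6:16, 16, TRUE), sample(6:16, 16, TRUE))
  stack <- lapply(seq_len(16), function(i)
    seeded_random_image(i, sizes[i, 1], sizes[i, 2]))
  single_source <- c("op.invert", "op.histnorm", "op.meangrey",
                     "op.histstats", "op.smooth", "op.regiongrow", "op.lbp")
  for (op in single_source) {
    ser <- execute_serial(stack, op)
    for (w in c(1L, 2L, 4L)) {
      par <- execute_parallel(stack, op, workers = w)
      expect_identical(par, ser, info = sprintf("%s workers=%d", op, w))
    }
  }
  # two-source operator over a stack of image pairs
  pairs <- lapply(seq_len(8), function(i) list(stack[[i]], stack[[i]]))
  ser <- execute_serial(pairs, "op.absdiff")
  expect_identical(execute_parallel(pairs, "op.absdiff", workers = 4L), ser)
  expect_error(execute_parallel(stack, "op.invert", workers = 0L),
               class = "stackops_parameter_error")
})

test_that("operators are virtualization-transparent", {
  store <- withr::local_tempdir()
  stack <- lapply(1:4, function(i) seeded_random_image(i + 50, 12, 10))
  virt <- lapply(stack, function(x) virtualize(data_item(x), store))
  for (op in c("op.invert", "op.histnorm", "op.histstats", "op.lbp",
               "op.regiongrow", "op.smooth", "op.meangrey")) {
    mem <- execute_serial(stack, op)
    dsk <- execute_serial(virt, op)
    expect_identical(dsk, mem, info = op)
  }
  sig <- signal_item(c(5, 9, 1, 7, 3))
  vsig <- virtualize(data_item(sig), store)
  expect_identical(execute(work_package("op.medfilt1d", list(vsig))),
                   execute(work_package("op.medfilt1d", list(sig))))
})

test_that("repeated execution of one work package is deterministic", {
  img <- seeded_random_image(99, 14, 14)
  wp <- work_package("op.lbp", list(img), list("Cells C" = 2L))
  expect_identical(execute(wp), execute(wp))
})

test_that("templates persist parameter blocks across save/load", {
  dir <- withr::local_tempdir()
  save_template("lbp-big", "op.lbp",
                list("Neighbours P" = 16L, "Radius R" = 2.0), dir = dir)
  tpl <- load_template("lbp-big", dir = dir)
  expect_identical(tpl$operator, "op.lbp")
  expect_equal(tpl$params[["Neighbours P"]], 16L)
  expect_equal(tpl$params[["Radius R"]], 2.0)
  expect_equal(tpl$params[["Smooth (Gaussian)"]], FALSE)  # defaults filled
  expect_error(load_template("missing", dir = dir),
               class = "stackops_not_found_error")
  expect_error(save_template("bad", "op.lbp",
                             list("Neighbours P" = 99L), dir = dir),
               class = "stackops_validation_error")
})
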