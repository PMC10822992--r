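test_that("annotation CSV and COCO JSON readers agree on the same boxes", {
  ann <- data.frame(image = rep(c("a.png", "b.png"), each = 2),
                    structure = rep(c("OD", "OC"), 2),
                    x_min = c(10, 20, 30, 40), y_min = c(11, 21, 31, 41),
                    x_max = c(50, 45, 70, 65), y_max = c(52, 46, 72, 66))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, csv)
  expect_identical(read_annotations(csv), ann)
  coco <- list(
    images = data.frame(id = 1:2, file_name = c("a.png", "b.png")),
    categories = data.frame(id = 1:2, name = c("optic disc", "optic cup")),
    annotations = data.frame(
      image_id = c(1, 1, 2, 2), category_id = c(1, 2, 1, 2),
      bbox = I(list(c(10, 11, 40, 41), c(20, 21, 25, 25),
                    c(30, 31, 40, 41), c(40, 41, 25, 25)))))
  json <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(coco, json, auto_unbox = TRUE)
  from_coco <- read_coco_annotations(json)
  expect_equal(from_coco[order(from_coco$image, from_coco$structure), ]$x_max,
               ann[order(ann$image, ann$structure), ]$x_max)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(image = "a", structure = "XX",
                              x_min = 0, y_min = 0, x_max = 1, y_max = 1),
                   bad, row.names = FALSE)
  expect_error(read_annotations(bad), "unknown structure")
})

test_that("oracle screening on ground-truth boxes is a perfect classifier", {
  cfg <- tiny_synth_config(image_size = 24)
  ds <- generate_fundus_dataset(cfg, n = 50, seed = 14)
  res <- run_screening(ds$samples, use_ground_truth = TRUE)
  expect_identical(nrow(res$records), 50L)
  expect_true(all(res$records$status == "ok"))
  expect_identical(res$report$confusion$accuracy, 1)
  expect_identical(res$report$roc$auc, 1)
  expect_equal(res$report$mean_iou, 1)  # boxes are the truth itself
  # diagnosis column equals the geometry rule applied to the ratio column
  expect_identical(res$records$diagnosis, diagnose(res$records$ratio))
  # rim width is the radius difference under the active convention
  expect_equal(res$records$rim_width,
               res$records$od_radius - res$records$oc_radius)
})

test_that("empty input and per-sample failures are isolated", {
  empty <- run_screening(character(0))
  expect_identical(nrow(empty$records), 0L)
  expect_null(empty$report)
  cfg <- tiny_synth_config(image_size = 24)
  d <- withr::local_tempdir()
  generate_fundus_dataset(cfg, n = 3, seed = 15, dir = d)
  paths <- c(file.path(d, "synthetic_0001.png"),
             file.path(d, "no_such_file.png"),
             file.path(d, "synthetic_0003.png"))
  res <- run_screening(paths, annotations = file.path(d, "annotations.csv"),
                       use_ground_truth = TRUE)
  expect_identical(res$records$status, c("ok", "failed", "ok"))
  expect_match(res$records$message[2], "not found")
  expect_identical(sum(res$records$status == "ok"), 2L)
})

test_that("screening with incompatible detector configs aborts", {
  cfg_a <- tiny_vit_config(projection_dim = 16, mlp_head_units = c(16))
  cfg_b <- tiny_vit_config(projection_dim = 8, mlp_head_units = c(16))
  ds <- generate_fundus_dataset(tiny_synth_config(), n = 2, seed = 16)
  tc <- train_config(epochs = 2, batch_size = 2, seed = 1)
  od <- train_vit(ds$samples, cfg_a, tc, structure = "od")
  oc <- train_vit(ds$samples, cfg_b, tc, structure = "oc")
  expect_error(run_screening(ds$samples, od_model = od, oc_model = oc),
               "incompatible")
  expect_error(run_screening(ds$samples, od_model = od, oc_model = NULL),
               "required")
})

test_that("screening runs are deterministic and serialise byte-identically", {
  cfg <- tiny_synth_config(image_size = 24)
  ds <- generate_fundus_dataset(cfg, n = 8, seed = 17)
  tcfg <- tiny_vit_config(image_size = 24, patch_size = 8,
                          projection_dim = 8, mlp_head_units = c(8))
  tc <- train_config(epochs = 3, batch_size = 4, seed = 2)
  od <- train_vit(ds$samples, tcfg, tc, structure = "od")
  oc <- train_vit(ds$samples, tcfg, tc, structure = "oc")
  r1 <- run_screening(ds$samples, od_model = od, oc_model = oc)
  r2 <- run_screening(ds$samples, od_model = od, oc_model = oc)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_screening_csv(r1, f1)
  write_screening_csv(r2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("reference ground-truth boxes replay to the printed display ratios", {
  t2 <- load_table2_fixture()
  for (i in 1:2) {  # the two self-consistent records
    oc <- as.numeric(t2[i, c("gt_oc_x_min", "gt_oc_y_min",
                             "gt_oc_x_max", "gt_oc_y_max")])
    od <- as.numeric(t2[i, c("gt_od_x_min", "gt_od_y_min",
                             "gt_od_x_max", "gt_od_y_max")])
    r <- compute_cdr(oc, od)
    expect_identical(r$display_ratio, t2$gt_ratio[i])
  }
})
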