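test_that("canonical CSV round trip is lossless, including extras", {
    tab <- LocalizationTable(x = c(10.5, 20.25, 30.125), y = c(1, 2, 3),
                             z = c(5, 6, 7), frame = c(2L, 1L, 2L),
                             photons = c(100, 200, 300), channel = c(1L, 2L, 1L),
                             sigma = 8,
                             extras = data.frame(score = c(0.1, 0.2, 0.3)))
    f <- withr::local_tempfile(fileext = ".csv")
    writeLocalizations(tab, f)
    back <- readLocalizations(f)
    d0 <- locData(tab)[order(locData(tab)$frame, locData(tab)$id), ]
    rownames(d0) <- NULL
    d1 <- locData(back)
    expect_equal(d1$x, d0$x)
    expect_equal(d1$z, d0$z)
    expect_equal(d1$photons, d0$photons)
    expect_equal(as.numeric(d1$score), d0$score)
    f2 <- withr::local_tempfile(fileext = ".csv")
    writeLocalizations(back, f2)
    expect_identical(readLines(f), readLines(f2))
})

test_that("micrometre input is converted to nm on read", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("id,frame,x_nm,y_nm,z_nm,photons,channel,sigma_nm",
                 "1,1,1.5,2.5,,100,1,"), f)
    tab <- readLocalizations(f, unit = "um")
    expect_equal(locData(tab)$x, 1500)
    expect_equal(locData(tab)$y, 2500)
})

test_that("a table without z reports 2 dimensions", {
    tab <- LocalizationTable(x = 1:5, y = 1:5)
    expect_identical(locDims(tab), 2L)
    expect_equal(ncol(locCoords(tab)), 2)
    f <- withr::local_tempfile(fileext = ".csv")
    writeLocalizations(tab, f)
    expect_identical(locDims(readLocalizations(f)), 2L)
})

test_that("ThunderSTORM-style headers are mapped", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c('"id","frame","x [nm]","y [nm]","intensity [photon]","uncertainty [nm]"',
                 "1,1,100,200,950,12",
                 "2,1,150,250,1050,9"), f)
    tab <- readLocalizations(f, dialect = "thunderstorm")
    expect_equal(locData(tab)$x, c(100, 150))
    expect_equal(locPhotons(tab), c(950, 1050))
    expect_equal(locData(tab)$sigma, c(12, 9))
})

test_that("missing columns and non-numeric cells give informative errors", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("id,frame,x_nm,photons,channel", "1,1,10,100,1"), f)
    expect_error(readLocalizations(f), "y_nm")
    f2 <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("id,frame,x_nm,y_nm,z_nm,photons,channel,sigma_nm",
                 "1,1,10,20,,100,1,",
                 "2,1,oops,20,,100,1,"), f2)
    expect_error(readLocalizations(f2), "line 3")
})

test_that("histogram binning follows the half-open floor convention", {
    tab <- LocalizationTable(x = 25, y = 25)
    img <- renderHistogram(tab, 20, bounds = c(0, 100, 0, 100))
    px <- pixelData(img)
    expect_equal(px[2, 2], 1)   # 0-based pixel index (1, 1)
    expect_equal(sum(px), 1)
    # two localizations 5 nm apart in one bin
    tab2 <- LocalizationTable(x = c(22, 27), y = c(25, 25))
    px2 <- pixelData(renderHistogram(tab2, 20, bounds = c(0, 100, 0, 100)))
    expect_equal(px2[2, 2], 2)
    expect_equal(sum(px2), 2)
    # a coordinate exactly on a bin edge belongs to the upper bin
    px3 <- pixelData(renderHistogram(LocalizationTable(x = 40, y = 0), 20,
                                     bounds = c(0, 100, 0, 100)))
    expect_equal(px3[3, 1], 1)
})

test_that("rendering conserves in-bounds counts on random tables", {
    sim <- shellField(nClusters = 3, nMol = 150, seed = 8)
    img <- renderHistogram(sim$table, 20)
    expect_equal(sum(pixelData(img)), length(sim$table))
    expect_error(renderHistogram(LocalizationTable(numeric(0), numeric(0)), 20),
                 "bounds")
})

test_that("PixelImage TIFF round trip preserves values beyond [0, 1]", {
    m <- matrix(rnorm(64, sd = 50), 8, 8)
    img <- PixelImage(m, 20, origin = c(100, -40))
    f <- withr::local_tempfile(fileext = ".tif")
    writePixelImage(img, f)
    back <- readPixelImage(f)
    expect_equal(pixelData(back), m, tolerance = 1e-6)
    expect_equal(pixelSize(back), 20)
    expect_equal(imageOrigin(back), c(100, -40))
})

test_that("MRC volume round trip preserves data and voxel size", {
    v <- array(rnorm(5^3), c(5, 5, 5))
    vol <- Volume3D(v, voxelSize = 8, origin = c(1, 2, 3))
    f <- withr::local_tempfile(fileext = ".mrc")
    writeVolumeMRC(vol, f)
    back <- readVolumeMRC(f)
    expect_equal(voxelData(back), v, tolerance = 1e-6)
    expect_equal(pixelSize(back), 8, tolerance = 1e-6)
})

test_that("cluster stacks survive a multi-page TIFF round trip", {
    imgs <- list(matrix(rnorm(25), 5, 5), matrix(rnorm(25), 5, 5))
    st <- ClusterStack(imgs, pixelSize = 20)
    f <- withr::local_tempfile(fileext = ".tif")
    writeClusterStack(st, f)
    back <- readClusterStack(f)
    expect_equal(stackImages(back)[[2]], imgs[[2]], tolerance = 1e-6)
})
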