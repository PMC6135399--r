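Package: chiagrowth
Title: Thermal-Time Growth Analysis and Deficit-Irrigation Scheduling for
    Chia (Salvia hispanica)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for functional growth analysis of chia (Salvia hispanica
    L.) field trials on a thermal-time axis: accumulation of growing degree
    days, FAO-56 Penman-Monteith reference evapotranspiration and
    deficit-irrigation scheduling by accumulated-ETo trigger, double-logistic
    fitting of biomass and leaf-area trajectories by damped least squares,
    classical (Hunt) and functional growth indices (RGR, NAR, LAR/LWR, CGR,
    SLW, LAI), one-way ANOVA with Duncan's multiple range test, and a
    seeded synthetic-trial generator emulating a sowing-date trial and a
    deficit-irrigation trial for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
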