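# Reference stenosed-arteriole run: cell-free platelet transit past the
# thrombus bump.  Units: um, s, mPa.s; see load_config() for the schema.
vessel.R = 7.5
vessel.L = 45
shape.a = 7.5
shape.b = 6
shape.h = 1.2
shape.z_c = 22.5
shape.kappa = 1.9
fluid.mu = 1.2
fluid.U_mean = 1128
cells.hct = 0
mesh.n_theta = 24
mesh.n_z = 48
platelet.x = 1
platelet.y = -0.6
platelet.z = 10
platelet.subdiv = 3
run.max_disp = 0.2
run.travel_target = 25
run.seed = 1
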