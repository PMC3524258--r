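# Canonical parameter set of the raft-compartment FcERI signaling model.
# Units: copy numbers in molecules/cell; bath association constants /M/s
# with bath species in molar; membrane-membrane association constants per
# (molecule/cell) per second; first-order constants /s.
#
# Provenance notes:
#  - copy numbers, site chemistry and off-rates follow the membrane-proximal
#    RBL-2H3 model of Faeder et al. 2003 (J Immunol 170:3769); Lyn is the
#    active receptor-available pool (Wofsy et al.).
#  - k_dephos = 20/s: naked ITAM phosphotyrosine mean lifetime <= 0.05 s.
#  - koff_syk: 0.2/s default (35% reduced receptor-Syk lifetime); the
#    original fit is 0.13/s.
#  - koff_lyn_sh2 = 0.12/s sets the ~6 s phospho-beta half-life.
#  - partition coefficients: 0.30 for non-aggregated receptors (raft area
#    fraction); 0.85 for aggregated receptors (Triton X-100 series of
#    Kovarova et al. 2001 extrapolated to zero detergent), Lyn and LAT.
#  - raft geometry: 100 nm radius, 30% coverage, 8e-6 cm^2 cell area
#    (~8,000 rafts/cell); raft diffusion 1e-8 cm^2/s (Pralle et al.).
#  - ligand/hapten, trans-phosphorylation scale and LAT Michaelis-Menten
#    constants are transcribed/calibrated against the printed behavioral
#    anchors (optimal dose ~5 nM; beta/gamma dephosphorylation half-lives
#    ~6/11 s; high-LAT regime); see the methods vignette.
rec_total: 4.0e+5
lyn_total: 2.8e+4
syk_total: 4.0e+5
lat_total: 1.0e+6
grb2_total: 1.0e+6
kon_lig: 1.0e+8
koff_lig: 0.5
kx_lig: 2.5e-4
koff_x: 0.5
kon_hapten: 1.0e+8
koff_hapten: 1.1
kon_lyn_u: 5.0e-5
koff_lyn_u: 20.0
kon_lyn_sh2: 2.0e-5
koff_lyn_sh2: 0.12
kon_syk: 6.0e-5
koff_syk: 0.2
kon_grb2: 5.0e-6
koff_grb2: 0.1
p_beta_u: 0.3
p_beta_s: 0.9
p_gamma_u: 1.0
p_gamma_s: 3.0
p_syk_u: 30.0
p_syk_s: 100.0
p_aloop: 100.0
p_aloop_a: 200.0
kcat_lat: 1.0
km_lat: 1.0e+6
k_dephos: 20.0
k_dephos_cyt: 20.0
alpha: 0.2
lyn_nonraft_activity: 0.2
cell_area: 8.0e-6
raft_radius: 100.0
raft_coverage: 0.30
raft_lifetime: 10.0
d_raft: 1.0e-8
rho_monomer: 0.30
rho_dimer: 0.85
rho_lyn: 0.85
rho_lat: 0.85
lyn_mutant: no
scale_bimolecular: yes
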