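clinic_id,n_clients,n_contacts,client_costs,staff_costs,materials_costs,net_suppressed
A,214,642,15515.00,164781.00,216614.00,22
B,106,700,1303.80,5819.24,10075.01,6
C,227,454,822.88,18287.84,5230.32,9
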