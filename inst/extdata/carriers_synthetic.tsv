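variant_id	family	id	aff	carrier
rs140757891	SF01	SF01_a_1	2	1
rs140757891	SF01	SF01_a_2	2	1
rs140757891	SF01	SF01_u_3	1	1
rs140757891	SF01	SF01_u_4	1	0
rs140757891	SF01	SF01_u_5	1	0
rs140757891	SF01	SF01_u_6	1	0
rs140757891	SF01	SF01_u_7	1	0
rs140757891	SF02	SF02_a_1	2	1
rs140757891	SF02	SF02_a_2	2	1
rs140757891	SF02	SF02_u_3	1	1
rs140757891	SF02	SF02_u_4	1	0
rs140757891	SF02	SF02_u_5	1	0
rs140757891	SF02	SF02_u_6	1	0
rs140757891	SF02	SF02_u_7	1	0
rs121909352	SF03	SF03_a_1	2	1
rs121909352	SF03	SF03_a_2	2	1
rs121909352	SF03	SF03_a_3	2	1
rs121909352	SF03	SF03_a_4	2	0
rs121909352	SF03	SF03_u_5	1	0
rs121909352	SF03	SF03_u_6	1	0
rs121909352	SF04	SF04_a_1	2	1
rs121909352	SF04	SF04_a_2	2	0
rs121909352	SF04	SF04_u_3	1	0
rs2302516	SF05	SF05_a_1	2	1
rs2302516	SF05	SF05_a_2	2	1
rs2302516	SF05	SF05_a_3	2	1
rs2302516	SF05	SF05_a_4	2	1
rs2302516	SF05	SF05_a_5	2	0
rs2302516	SF05	SF05_a_6	2	0
rs2302516	SF05	SF05_u_7	1	1
rs2302516	SF05	SF05_u_8	1	0
rs2302516	SF05	SF05_u_9	1	0
rs2302516	SF05	SF05_u_10	1	0
rs2302516	SF05	SF05_u_11	1	0
rs2302516	SF05	SF05_u_12	1	0
rs2302516	SF05	SF05_u_13	1	0
rs2302516	SF06	SF06_a_1	2	1
rs2302516	SF06	SF06_a_2	2	1
rs2302516	SF06	SF06_a_3	2	1
rs2302516	SF06	SF06_a_4	2	0
rs2302516	SF06	SF06_a_5	2	0
rs2302516	SF06	SF06_u_6	1	0
rs2302516	SF06	SF06_u_7	1	0
rs2302516	SF06	SF06_u_8	1	0
rs2302516	SF06	SF06_u_9	1	0
rs2302516	SF06	SF06_u_10	1	0
rs2302516	SF06	SF06_u_11	1	0
rs2302516	SF06	SF06_u_12	1	0
g.406+2780C>T	SF07	SF07_a_1	2	1
g.406+2780C>T	SF07	SF07_a_2	2	1
g.406+2780C>T	SF07	SF07_u_3	1	1
g.406+2780C>T	SF07	SF07_u_4	1	0
g.18328T>G	SF08	SF08_a_1	2	1
g.18328T>G	SF08	SF08_a_2	2	0
g.18328T>G	SF08	SF08_u_3	1	1
g.18328T>G	SF08	SF08_u_4	1	0
g.15169-59T>A	SF08	SF08_a_1	2	1
g.15169-59T>A	SF08	SF08_a_2	2	0
g.15169-59T>A	SF08	SF08_u_3	1	1
g.15169-59T>A	SF08	SF08_u_4	1	0
rs112542818	SF09	SF09_a_1	2	1
rs112542818	SF09	SF09_a_2	2	1
rs112542818	SF09	SF09_a_3	2	1
rs112542818	SF09	SF09_a_4	2	0
rs112542818	SF09	SF09_a_5	2	0
rs112542818	SF09	SF09_u_6	1	1
rs112542818	SF09	SF09_u_7	1	0
rs112542818	SF10	SF10_a_1	2	1
rs112542818	SF10	SF10_a_2	2	1
rs112542818	SF10	SF10_a_3	2	0
rs112542818	SF10	SF10_u_4	1	1
rs112542818	SF10	SF10_u_5	1	0
rs148861809	SF11	SF11_a_1	2	1
rs148861809	SF11	SF11_a_2	2	1
rs148861809	SF11	SF11_a_3	2	1
rs148861809	SF11	SF11_a_4	2	1
rs148861809	SF11	SF11_a_5	2	0
rs148861809	SF11	SF11_a_6	2	0
rs148861809	SF11	SF11_u_7	1	1
rs148861809	SF11	SF11_u_8	1	1
rs148861809	SF11	SF11_u_9	1	0
rs148861809	SF11	SF11_u_10	1	0
rs148861809	SF11	SF11_u_11	1	0
rs148861809	SF12	SF12_a_1	2	1
rs148861809	SF12	SF12_a_2	2	1
rs148861809	SF12	SF12_a_3	2	1
rs148861809	SF12	SF12_a_4	2	0
rs148861809	SF12	SF12_u_5	1	1
rs148861809	SF12	SF12_u_6	1	0
rs148861809	SF12	SF12_u_7	1	0
g.syn_noaff	SF13	SF13_u_1	1	1
g.syn_noaff	SF13	SF13_u_2	1	0
g.syn_noaff	SF13	SF13_u_3	1	0
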