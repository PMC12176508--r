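code	label	site
C50	Breast cancer	breast
C73	Thyroid cancer	endocrine
C74	Adrenal cancer	endocrine
C75	Other endocrine gland cancer	endocrine
C15	Esophageal cancer	gastrointestinal
C16	Gastric cancer	gastrointestinal
C17	Small intestine cancer	gastrointestinal
C18	Colon cancer	gastrointestinal
C19	Rectosigmoid cancer	gastrointestinal
C20	Rectal cancer	gastrointestinal
C21	Anal cancer	gastrointestinal
C22	Liver and bile duct cancer	gastrointestinal
C23	Gallbladder cancer	gastrointestinal
C24	Biliary tract cancer	gastrointestinal
C25	Pancreatic cancer	gastrointestinal
C26	Other digestive organ cancer	gastrointestinal
C60	Penile cancer	genitourinary
C61	Prostate cancer	genitourinary
C62	Testicular cancer	genitourinary
C64	Renal cancer	genitourinary
C65	Renal pelvis cancer	genitourinary
C66	Ureter cancer	genitourinary
C67	Bladder cancer	genitourinary
C68	Other urinary organ cancer	genitourinary
C51	Vulvar cancer	gynecologic
C52	Vaginal cancer	gynecologic
C53	Cervical cancer	gynecologic
C54	Uterine corpus cancer	gynecologic
C55	Uterine cancer unspecified	gynecologic
C56	Ovarian cancer	gynecologic
C57	Other female genital cancer	gynecologic
C00	Lip cancer	head_and_neck
C01	Base of tongue cancer	head_and_neck
C02	Tongue cancer	head_and_neck
C03	Gum cancer	head_and_neck
C04	Floor of mouth cancer	head_and_neck
C05	Palate cancer	head_and_neck
C06	Other mouth cancer	head_and_neck
C07	Parotid gland cancer	head_and_neck
C08	Other salivary gland cancer	head_and_neck
C09	Tonsil cancer	head_and_neck
C10	Oropharyngeal cancer	head_and_neck
C11	Nasopharyngeal cancer	head_and_neck
C12	Pyriform sinus cancer	head_and_neck
C13	Hypopharyngeal cancer	head_and_neck
C14	Other oral cavity and pharynx cancer	head_and_neck
C30	Nasal cavity cancer	head_and_neck
C31	Accessory sinus cancer	head_and_neck
C32	Laryngeal cancer	head_and_neck
C81	Hodgkin lymphoma	hematologic
C82	Follicular lymphoma	hematologic
C83	Non-follicular lymphoma	hematologic
C84	T-cell lymphoma	hematologic
C85	Other non-Hodgkin lymphoma	hematologic
C88	Malignant immunoproliferative disease	hematologic
C90	Multiple myeloma	hematologic
C91	Lymphoid leukemia	hematologic
C92	Myeloid leukemia	hematologic
C93	Monocytic leukemia	hematologic
C94	Other specified leukemia	hematologic
C95	Leukemia unspecified	hematologic
C96	Other hematopoietic cancer	hematologic
C33	Tracheal cancer	lung
C34	Lung and bronchus cancer	lung
C37	Thymic cancer	lung
C38	Heart mediastinum and pleura cancer	lung
C39	Other respiratory cancer	lung
C43	Malignant melanoma of skin	melanoma
C70	Meningeal cancer	nervous_system
C71	Brain cancer	nervous_system
C72	Spinal cord and CNS cancer	nervous_system
C40	Bone and articular cartilage cancer	sarcoma
C41	Bone cancer other sites	sarcoma
C45	Mesothelioma	sarcoma
C46	Kaposi sarcoma	sarcoma
C47	Peripheral nerve sarcoma	sarcoma
C48	Retroperitoneum and peritoneum cancer	sarcoma
C49	Soft tissue sarcoma	sarcoma
C44	Other malignant neoplasm of skin	skin_other
C4A	Merkel cell carcinoma	skin_other
C76	Other solid tumor	excluded
C77	Lymph node disease	excluded
C78	Metastatic	excluded
C79	Metastatic	excluded
C80.0	Other solid tumor with distant metastatic	excluded
C80.1	Unspecified	excluded
C80	Unspecified	excluded
D36	Benign neoplasm	excluded
D37	Neoplasm of uncertain or unspecific behavior	excluded
D48	Neoplasm of uncertain or unspecific behavior	excluded
D49	Neoplasm of uncertain or unspecific behavior	excluded
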